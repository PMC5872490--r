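# Shared in-code fixtures. Everything is generated at test time; no
# binary data is stored.

# Tiny two-line / two-attribute profile with well-separated means.
toy_profile <- function(cv = 0.1) {
  mu <- rbind(c(100, 1000), c(1000, 100))
  cell_line_profile(c("A", "B"), mu, cv * mu, c("x", "y"))
}

# Single-line, single-attribute profile (mu = sigma = 100).
unit_profile <- function() {
  suppressWarnings(cell_line_profile("A", matrix(100), matrix(100), "x"))
}

# Deterministic n x m profile with positive sigmas, for schema-level tests.
grid_profile <- function(n = 3, m = 4) {
  mu <- outer(seq_len(n), seq_len(m), function(i, j) 100 * i + 10 * j)
  cell_line_profile(paste0("L", seq_len(n)), mu, 0.2 * mu,
                    paste0("a", seq_len(m)))
}
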