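# fixture builders shared across test files; everything is generated in code

# one small deterministic cell table: trees x years x files of linear
# tracheidogram profiles (no noise)
tiny_cells <- function(trees = "T01", years = 2000:2001, n_files = 10L,
                       n_cells = 10L) {
  rows <- list()
  for (tr in trees) {
    for (y in years) {
      for (f in seq_len(n_files)) {
        ld <- seq(22, 4, length.out = n_cells)
        cwt <- seq(3, 5, length.out = n_cells)
        rows[[length(rows) + 1L]] <- data.frame(
          tree = tr, core = paste0(tr, "A"), year = y,
          file = sprintf("F%02d", f), rank = seq_len(n_cells),
          ld = ld, cwt = cwt, stringsAsFactors = FALSE)
      }
    }
  }
  as_qwa_cells(do.call(rbind, rows))
}

# random monthly climate table with a fixed seed
random_climate <- function(variable = "tmax", years = 1962:2019, seed = 1L,
                           mean = 15, sd = 2) {
  set.seed(seed)
  qwa_climate(variable, years,
              matrix(stats::rnorm(length(years) * 12L, mean, sd),
                     length(years), 12L))
}

# sector matrix object built directly from arrays (bypasses cell level)
manual_sector_matrix <- function(ld_arr, cwt_arr = ld_arr / 4, trees, years) {
  S <- dim(ld_arr)[3L]
  structure(list(ld = ld_arr, cwt = cwt_arr,
                 depth = matrix(10L, length(trees), length(years),
                                dimnames = list(trees, years)),
                 n_interpolated = matrix(0L, length(trees), length(years)),
                 trees = trees, years = years, n_sectors = S,
                 removed = data.frame()),
            class = "qwa_sector_matrix")
}

# amplitude of the sinusoid of wavelength `wv` in series v (trend-aware)
sin_amplitude <- function(v, t, wv) {
  cc <- cos(2 * pi * t / wv)
  ss <- sin(2 * pi * t / wv)
  f <- stats::lm(v ~ t + cc + ss)
  sqrt(sum(stats::coef(f)[3:4]^2))
}
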