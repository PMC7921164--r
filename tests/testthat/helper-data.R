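# small longitudinal datasets built in code
make_dataset <- function(obs = c("y1", "y2"), times = c(0, 1, 2, 4, 7),
                         means = NULL, sds = NULL, kind = "metabolic", n = 6L) {
  grid <- expand.grid(observable = obs, time = times,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$observable, grid$time), ]
  if (is.null(means)) means <- 10 + seq_len(nrow(grid))
  if (is.null(sds)) sds <- rep(1, nrow(grid))
  longitudinal_dataset(tibble::tibble(
    observable = grid$observable, kind = kind, time = grid$time,
    mean = means, sd = sds, n = n))
}
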