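# Small shared fixtures; everything is generated in code at test time.

tiny_montage <- function() {
  tibble::tibble(channel = c("L", "R"), x = c(-0.5, 0.5), y = c(0, 0))
}

small_montage <- function(n = 8) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(channel = sprintf("ch%02d", seq_len(n)),
                 x = 0.8 * cos(theta), y = 0.8 * sin(theta))
}

# condition_erp table built from an explicit subject x cell list of maps
erps_from_maps <- function(maps_by_subject, times_ms = NULL, montage = NULL) {
  rows <- purrr::imap_dfr(maps_by_subject, function(cells, subj) {
    tibble::tibble(
      subject = subj,
      category = NA_character_,
      cell = names(cells),
      is_repetition = grepl("Rep$", names(cells)),
      is_expected = grepl("^Exp", names(cells)),
      n_trials = 1L,
      map = unname(cells)
    )
  })
  times_ms <- times_ms %||% seq_len(ncol(rows$map[[1]]))
  erptopo::as_condition_erp(rows, times_ms, montage)
}

design_cells <- c("Exp_Rep", "Exp_Alt", "Unexp_Rep", "Unexp_Alt")

# random average-referenced map
random_avg_ref_map <- function(n_ch) {
  v <- rnorm(n_ch)
  v - mean(v)
}
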