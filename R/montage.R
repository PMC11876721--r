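# Idealized 10-10 scalp montage on the unit disc. Rows are anterior-posterior
# lines of the extended 10-20 nomenclature; y is the AP coordinate, x the
# lateral coordinate (left negative), both scaled to keep every electrode
# inside the unit circle.

ten_ten_rows <- list(
  Fp  = list(y = 0.90, labels = c("Fp1", "Fpz", "Fp2"),
             lat = c(-0.3, 0, 0.3)),
  AF  = list(y = 0.70, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
             lat = c(-0.7, -0.3, 0, 0.3, 0.7)),
  F   = list(y = 0.50,
             labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
             lat = c(-0.7, -0.5, -0.35, -0.18, 0, 0.18, 0.35, 0.5, 0.7)),
  FC  = list(y = 0.25,
             labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
             lat = c(-0.8, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8)),
  C   = list(y = 0.00,
             labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
             lat = c(-0.9, -0.65, -0.45, -0.22, 0, 0.22, 0.45, 0.65, 0.9)),
  CP  = list(y = -0.25,
             labels = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10"),
             lat = c(-0.95, -0.8, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 0.95)),
  P   = list(y = -0.50,
             labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
             lat = c(-0.7, -0.5, -0.35, -0.18, 0, 0.18, 0.35, 0.5, 0.7)),
  PO  = list(y = -0.70, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
             lat = c(-0.7, -0.3, 0, 0.3, 0.7)),
  O   = list(y = -0.90, labels = c("O1", "Oz", "O2"),
             lat = c(-0.3, 0, 0.3)),
  Iz  = list(y = -0.98, labels = "Iz", lat = 0)
)

ten_ten_table <- function() {
  rows <- lapply(ten_ten_rows, function(r) {
    half_width <- sqrt(pmax(0, 1 - r$y^2)) * 0.95
    tibble::tibble(channel = r$labels, x = r$lat * half_width, y = r$y)
  })
  dplyr::bind_rows(rows)
}

# standard 32-channel subset of the 64-channel cap
ten_ten_32 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO7", "POz", "PO8", "O1", "O2"
)

#' Build a scalp electrode montage
#'
#' Returns an idealized 10-10 montage as a tibble of channel labels with 2-D
#' positions on the unit disc (nose up, left negative x). The default is the
#' full 64-channel layout; `n_channels = 32` selects the standard 32-channel
#' subset. Custom montages can be supplied as a data frame with columns
#' `channel`, `x`, `y` to any function that takes a montage.
#'
#' @param n_channels Either 64 (default) or 32.
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' make_montage()
#' make_montage(32)
#' @export
make_montage <- function(n_channels = 64) {
  full <- ten_ten_table()
  if (n_channels == 64) {
    out <- full
  } else if (n_channels == 32) {
    out <- full[match(ten_ten_32, full$channel), ]
  } else {
    rlang::abort("`n_channels` must be 64 or 32; supply a custom data frame for other layouts.")
  }
  validate_montage(out)
}

validate_montage <- function(montage) {
  montage <- tibble::as_tibble(montage)
  stopifnot(all(c("channel", "x", "y") %in% names(montage)))
  if (anyDuplicated(montage$channel) > 0) {
    rlang::abort("montage channel labels must be unique")
  }
  if (nrow(montage) < 2) rlang::abort("a montage needs at least 2 channels")
  if (!all(is.finite(montage$x)) || !all(is.finite(montage$y))) {
    rlang::abort("montage positions must be finite")
  }
  montage
}

# pairwise Euclidean electrode distances in montage (unit-disc) units
montage_distances <- function(montage) {
  montage <- validate_montage(montage)
  d <- as.matrix(stats::dist(cbind(montage$x, montage$y)))
  dimnames(d) <- list(montage$channel, montage$channel)
  d
}
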