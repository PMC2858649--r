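#' Standard 60-channel EEG montage used by the synthetic generator
#'
#' Extended 10-20 labels with approximate flattened scalp coordinates
#' (x: left negative to right positive; y: posterior negative to anterior
#' positive; arbitrary head-radius units). Includes F8 (muscle-artifact
#' monitor channel) and P1. The vertical EOG channel is appended separately
#' by the generator and is not part of this montage.
#'
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
tep_montage <- function() {
  rows <- list(
    Fp  = list(y = 4.0,  labs = c("Fp1", "Fpz", "Fp2"),                xs = c(-0.75, 0, 0.75)),
    AF  = list(y = 3.2,  labs = c("AF7", "AF3", "AF4", "AF8"),         xs = c(-2.0, -0.9, 0.9, 2.0)),
    F   = list(y = 2.4,  labs = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
               xs = c(-3, -2.25, -1.5, -0.75, 0, 0.75, 1.5, 2.25, 3)),
    FC  = list(y = 1.2,  labs = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
               xs = c(-3.4, -2.25, -1.5, -0.75, 0, 0.75, 1.5, 2.25, 3.4)),
    C   = list(y = 0.0,  labs = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
               xs = c(-3.6, -2.25, -1.5, -0.75, 0, 0.75, 1.5, 2.25, 3.6)),
    CP  = list(y = -1.2, labs = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
               xs = c(-3.4, -2.25, -1.5, -0.75, 0, 0.75, 1.5, 2.25, 3.4)),
    P   = list(y = -2.4, labs = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
               xs = c(-3, -2.25, -1.5, -0.75, 0, 0.75, 1.5, 2.25, 3)),
    PO  = list(y = -3.2, labs = c("PO7", "PO3", "POz", "PO4", "PO8"),  xs = c(-2.0, -0.9, 0, 0.9, 2.0)),
    O   = list(y = -4.0, labs = c("O1", "Oz", "O2"),                   xs = c(-0.75, 0, 0.75))
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r$labs, x = r$xs, y = r$y, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

# Positions for an arbitrary subset of montage labels (used for spatial
# amplitude maps and noise mixing). Errors on labels outside the montage.
montage_positions <- function(labels) {
  m <- tep_montage()
  idx <- match(labels, m$label)
  if (anyNA(idx)) {
    stop("labels not in montage: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  cbind(x = m$x[idx], y = m$y[idx])
}
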