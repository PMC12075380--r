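#' Standard 10-10 montage used by the synthetic generator
#'
#' Returns the 64 electrode labels of the extended 10-20 (10-10) system used
#' throughout the package: the 50 electrodes that make up the eight scalp
#' regions of [region_map()], plus 8 midline and 6 lateral-rim sites.
#'
#' @param n_channels Number of channels requested (<= 64). The region
#'   electrodes come first so that reduced montages still resolve the
#'   frontal and occipital regions used in coupling analyses.
#' @return Character vector of channel names.
#' @export
montage_1010 <- function(n_channels = 64) {
  region_electrodes <- unlist(region_map(), use.names = FALSE)
  extras <- c("Fpz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz",
              "FT9", "FT10", "TP9", "TP10", "P9", "P10")
  full <- c(region_electrodes, extras)
  stopifnot(!anyDuplicated(full))
  if (!is.numeric(n_channels) || length(n_channels) != 1 ||
      n_channels < 1 || n_channels > length(full)) {
    stop("n_channels must be between 1 and ", length(full))
  }
  full[seq_len(n_channels)]
}

#' Electrode-to-region map
#'
#' The eight scalp regions (left/right frontal, central, temporal, occipital)
#' with their electrode allocations, used to average signals within a region
#' before band-power and coupling estimation.
#'
#' @return Named list of character vectors (region -> electrode labels).
#' @export
region_map <- function() {
  list(
    left_frontal   = c("Fp1", "AF3", "AF7", "F1", "F3", "F5", "F7",
                       "FC1", "FC3", "FC5"),
    right_frontal  = c("Fp2", "AF4", "AF8", "F2", "F4", "F6", "F8",
                       "FC2", "FC4", "FC6"),
    left_central   = c("C1", "C3", "C5", "CP1", "CP3", "CP5"),
    right_central  = c("C2", "C4", "C6", "CP2", "CP4", "CP6"),
    left_temporal  = c("FT7", "T7", "TP7"),
    right_temporal = c("FT8", "T8", "TP8"),
    left_occipital = c("P3", "P5", "P7", "PO3", "PO7", "O1"),
    right_occipital = c("P4", "P6", "P8", "PO4", "PO8", "O2")
  )
}

validate_region_map <- function(regions, channel_names) {
  stopifnot(is.list(regions), length(names(regions)) == length(regions))
  all_el <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_el)) {
    stop("region map assigns an electrode to two regions: ",
         paste(unique(all_el[duplicated(all_el)]), collapse = ", "))
  }
  missing <- setdiff(all_el, channel_names)
  if (length(missing)) {
    stop("region map electrode(s) not in montage: ",
         paste(missing, collapse = ", "))
  }
  invisible(regions)
}
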