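#' Standard 16-channel 10-20 montage
#'
#' Channel labels of the 16-electrode subset of the international 10-20
#' system used for bedside monitoring (no midline electrodes). Odd indices
#' are left-hemisphere, even indices right-hemisphere.
#'
#' @return Character vector of 16 channel labels.
#' @export
ten_twenty_16 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
}

#' Homologous left/right electrode pairs
#'
#' Resolves left/right homologous pairs from 10-20 labels: a label ending in
#' an odd digit is left-sided and its homolog is the same site with the next
#' even digit (Fp1/Fp2, T3/T4, ...).
#'
#' @param labels character vector of 10-20 channel labels.
#' @return data.frame with columns `left` and `right`.
#' @export
homologous_pairs <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  site <- sub("[0-9]+$", "", labels)
  left <- which(!is.na(num) & num %% 2 == 1)
  out <- lapply(left, function(i) {
    j <- which(site == site[i] & num == num[i] + 1)
    if (length(j) == 1) data.frame(left = labels[i], right = labels[j],
                                   stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop_nm("no homologous left/right pairs resolvable from labels")
  out
}

#' Default bipolar derivation chains for the 16-channel montage
#'
#' Anterior-posterior bipolar chains (parasagittal and temporal) per
#' hemisphere; the hemispheric symmetry index is computed on these
#' derivations. Returned as an explicit pair table so the derivation is
#' always visible configuration, never inferred silently.
#'
#' @return data.frame with columns `left_a`, `left_b`, `right_a`, `right_b`;
#'   row k defines the left bipolar channel `left_a-left_b` and its right
#'   homolog `right_a-right_b`.
#' @export
bipolar_chains_16 <- function() {
  data.frame(
    left_a  = c("Fp1", "F3", "C3", "P3", "Fp1", "F7", "T3", "T5"),
    left_b  = c("F3", "C3", "P3", "O1", "F7", "T3", "T5", "O1"),
    right_a = c("Fp2", "F4", "C4", "P4", "Fp2", "F8", "T4", "T6"),
    right_b = c("F4", "C4", "P4", "O2", "F8", "T4", "T6", "O2"),
    stringsAsFactors = FALSE
  )
}

#' Re-reference a recording to bipolar derivations
#'
#' Subtracts electrode pairs along the chains in `chains`, producing a new
#' recording whose channels are named `"A-B"`. Left and right derivations
#' are interleaved left-first in chain order.
#'
#' @param rec an [eeg_recording].
#' @param chains pair table as returned by [bipolar_chains_16()].
#' @return an [eeg_recording] of bipolar channels.
#' @export
derive_bipolar <- function(rec, chains = bipolar_chains_16()) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- unique(c(chains$left_a, chains$left_b, chains$right_a, chains$right_b))
  missing <- setdiff(need, rec$channel_labels)
  if (length(missing))
    stop_nm("missing electrodes for bipolar derivation: ",
            paste(missing, collapse = ", "))
  ch <- function(a, b) rec$data[a, , drop = TRUE] - rec$data[b, , drop = TRUE]
  labs <- character(0); rows <- list()
  for (k in seq_len(nrow(chains))) {
    labs <- c(labs, paste0(chains$left_a[k], "-", chains$left_b[k]),
              paste0(chains$right_a[k], "-", chains$right_b[k]))
    rows <- c(rows, list(ch(chains$left_a[k], chains$left_b[k])),
              list(ch(chains$right_a[k], chains$right_b[k])))
  }
  eeg_recording(do.call(rbind, rows), fs = rec$fs, channel_labels = labs,
                artifact_mask = rec$artifact_mask,
                meta = c(rec$meta, list(reference = "bipolar")))
}

#' Symmetry-index pair list from bipolar chains
#'
#' @param chains pair table as returned by [bipolar_chains_16()].
#' @return data.frame with `right` and `left` bipolar channel names.
#' @export
bsi_pairs_16 <- function(chains = bipolar_chains_16()) {
  data.frame(
    right = paste0(chains$right_a, "-", chains$right_b),
    left = paste0(chains$left_a, "-", chains$left_b),
    stringsAsFactors = FALSE
  )
}
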