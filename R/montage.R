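#' Standard 32-channel 10/20 montage
#'
#' Ordered channel labels of the default 32-electrode 10/20 cap used throughout
#' the package (CPz reference, nasal-tip ground; neither is a data channel).
#'
#' @return Character vector of 32 channel labels.
#' @export
#' @examples
#' montage_1020_32()
montage_1020_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "O2")
}

# Lobe groups follow the conventional 10/20 prefix reading:
# Fp/AF/F -> frontal, FC/C -> central, FT/T/TP -> temporal,
# CP/P -> parietal, PO/O -> occipital.
.lobe_map <- c(
  Fp = "frontal", AF = "frontal", F = "frontal",
  FC = "central", C = "central",
  FT = "temporal", T = "temporal", TP = "temporal",
  CP = "parietal", P = "parietal",
  PO = "occipital", O = "occipital"
)

#' Map 10/20 channel labels to scalp regions
#'
#' Hemisphere comes from the numeric suffix (odd = left, even = right,
#' trailing `z` = midline); the lobe from the leading letters (`Fp`/`AF`/`F`
#' frontal, `FC`/`C` central, `FT`/`T`/`TP` temporal, `CP`/`P` parietal,
#' `PO`/`O` occipital). "Posterior" in reports is parietal plus occipital.
#'
#' @param labels Character vector of 10/20 channel labels.
#' @return A tibble with columns `channel`, `hemisphere`, `lobe`, `region`
#'   (e.g. `"left frontal"`).
#' @export
#' @examples
#' channel_regions(c("F3", "F4", "Cz", "PO8"))
channel_regions <- function(labels) {
  stopifnot(is.character(labels), length(labels) > 0L)
  m <- regmatches(labels, regexec("^(Fp|AF|FC|FT|TP|CP|PO|F|C|T|P|O)([0-9]+|z)$", labels))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    abort(sprintf("channel label(s) not parseable as 10/20: %s",
                  paste(labels[bad], collapse = ", ")))
  }
  prefix <- vapply(m, `[`, "", 2L)
  suffix <- vapply(m, `[`, "", 3L)
  hemi <- rep("mid", length(labels))
  num <- suffix != "z"
  hemi[num] <- ifelse(as.integer(suffix[num]) %% 2L == 1L, "left", "right")
  lobe <- unname(.lobe_map[prefix])
  tibble::tibble(channel = labels, hemisphere = hemi, lobe = lobe,
                 region = paste(hemi, lobe))
}
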