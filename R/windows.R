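# Sequence-window handling: centralized 13-mers with the phosphoacceptor at
# position 0 and "J" padding where the window runs past the protein termini.

#' Extract a centralized sequence window around a phosphosite
#'
#' Returns the `(2 * flank + 1)`-mer of the protein sequence centered on
#' `site_position` (1-based). Positions beyond the protein termini are filled
#' with the placeholder `"J"`, so the phosphoacceptor always sits at window
#' position 0 (string index `flank + 1`).
#'
#' @param protein_sequence Single string of one-letter residue codes.
#' @param site_position 1-based position of the phosphoacceptor within
#'   `protein_sequence`.
#' @param flank Number of residues on each side of the site (default 6,
#'   giving the standard 13-mer).
#' @return A single string of length `2 * flank + 1`.
#' @export
#' @examples
#' centralize_site("MKSAPR", 3)            # "JJJJMKSAPRJJJ"
#' centralize_site("AAAAAAASAAAAAAA", 8)   # "AAAAAASAAAAAA"
centralize_site <- function(protein_sequence, site_position, flank = 6L) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L)
  if (!is.numeric(flank) || length(flank) != 1L || flank < 1L) {
    stop("`flank` must be a single integer >= 1", call. = FALSE)
  }
  flank <- as.integer(flank)
  len <- nchar(protein_sequence)
  if (!is.numeric(site_position) || length(site_position) != 1L ||
      site_position < 1L || site_position > len) {
    stop(sprintf("`site_position` %s is outside the protein (length %d)",
                 format(site_position), len), call. = FALSE)
  }
  site_position <- as.integer(site_position)
  lo <- site_position - flank
  hi <- site_position + flank
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - len)
  core <- substr(protein_sequence, max(1L, lo), min(len, hi))
  paste0(strrep(PAD_CHAR, left_pad), core, strrep(PAD_CHAR, right_pad))
}

# Window length implied by a window string (odd by construction).
window_flank <- function(window) (nchar(window) - 1L) %/% 2L

#' Residue at a signed window position
#'
#' @param window Window string (odd length, phosphoacceptor at position 0).
#' @param pos Signed position, `-flank ... +flank`.
#' @return Single-character residue code (may be `"J"`).
#' @export
window_residue <- function(window, pos) {
  flank <- window_flank(window)
  if (any(abs(pos) > flank)) {
    stop("position outside the window", call. = FALSE)
  }
  substring(window, flank + 1L + pos, flank + 1L + pos)
}

#' Check that a window is a well-formed centralized phosphosite window
#'
#' A valid window has odd length (13 by default usage), a phosphoacceptor
#' (S, T, or Y) at position 0, only standard residues or `"J"` elsewhere, and
#' `"J"` confined to contiguous runs at the start and/or end.
#'
#' @param window Character vector of window strings.
#' @param width Required window width (default 13). `NA` accepts any odd width.
#' @return Logical vector.
#' @export
is_valid_window <- function(window, width = 13L) {
  vapply(window, function(w) {
    n <- nchar(w)
    if (!is.na(width) && n != width) return(FALSE)
    if (n %% 2L == 0L) return(FALSE)
    chars <- strsplit(w, "")[[1]]
    if (!all(chars %in% c(AA_STANDARD, PAD_CHAR))) return(FALSE)
    if (!chars[(n + 1L) %/% 2L] %in% RESIDUE_CLASSES$Delta) return(FALSE)
    # "J" only as contiguous leading/trailing padding
    grepl(paste0("^", PAD_CHAR, "*[A-IK-Z]+", PAD_CHAR, "*$"), w)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Validate that a window's central residue matches a reported phosphoacceptor
#'
#' @param window Window string.
#' @param reported_residue One of `"S"`, `"T"`, `"Y"`.
#' @return `TRUE` iff the residue at position 0 equals `reported_residue`.
#' @export
#' @examples
#' validate_site_match("AAAAAASPAAAAA", "S")  # TRUE
#' validate_site_match("AAAAAATPAAAAA", "S")  # FALSE
validate_site_match <- function(window, reported_residue) {
  window_residue(window, 0L) == reported_residue
}
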