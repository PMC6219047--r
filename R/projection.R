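# Projection profiles and support statistics of binary masks.
#
# Collapsing the reagent mask along one axis gives a profile of foreground
# counts; the number of non-zero positions of the row profile is the
# "volume length", the quantity calibrated against pump steps. The support
# centre of the column profile locates the tip and the first non-zero row of
# a holder mask locates the holder, the localisation checks used to detect a
# missing or misaligned tip.

#' Row (horizontal) projection profile
#'
#' Counts foreground pixels in each row of a binary mask: the mask is
#' projected horizontally onto the vertical axis, so each vertical position
#' carries the width of the reagent at that height.
#'
#' @param mask A 0/1 matrix.
#' @return A tibble with one row per mask row: `position` (1-based row index)
#'   and `count`. Carries an `axis` attribute (`"row"`).
#' @export
row_profile <- function(mask) {
  assert_mask(mask)
  out <- tibble(position = seq_len(nrow(mask)), count = as.integer(rowSums(mask)))
  attr(out, "axis") <- "row"
  out
}

#' Column (vertical) projection profile
#'
#' Mirror of [row_profile()] over columns: `column_profile(m)` equals
#' `row_profile(t(m))`.
#'
#' @inheritParams row_profile
#' @return A tibble with `position` (1-based column index) and `count`;
#'   `axis` attribute `"column"`.
#' @export
column_profile <- function(mask) {
  assert_mask(mask)
  out <- tibble(position = seq_len(ncol(mask)), count = as.integer(colSums(mask)))
  attr(out, "axis") <- "column"
  out
}

#' Support statistics of a projection profile
#'
#' The support of a profile is the set of positions with a non-zero count.
#' Its size (`support_length`) ignores contiguity: interior gaps reduce the
#' length, which is why the mask is median-filtered upstream. The `center` is
#' the floor of the midpoint of the first and last non-zero positions
#' (deterministic tie-break for even spans).
#'
#' @param profile A tibble from [row_profile()]/[column_profile()], or a bare
#'   numeric vector of counts (positions then taken as `1:length`).
#' @return A one-row tibble: `support_length`, `first_nonzero`,
#'   `last_nonzero`, `center`. The three indices are `NA` for an all-zero
#'   profile (an "absent" outcome, not an error).
#' @examples
#' support_stats(c(0, 3, 5, 0, 2))
#' @export
support_stats <- function(profile) {
  if (is.data.frame(profile)) {
    counts <- profile$count
    positions <- profile$position
    if (is.null(counts)) abort("`profile` must have a `count` column.")
    if (is.null(positions)) positions <- seq_along(counts)
  } else if (is.numeric(profile)) {
    counts <- profile
    positions <- seq_along(counts)
  } else {
    abort("`profile` must be a profile tibble or a numeric vector of counts.")
  }
  if (any(is.na(counts)) || any(counts < 0)) abort("Profile counts must be non-negative.")
  nz <- positions[counts > 0]
  if (length(nz) == 0L) {
    return(tibble(support_length = 0L, first_nonzero = NA_integer_,
                  last_nonzero = NA_integer_, center = NA_integer_))
  }
  first <- as.integer(min(nz)); last <- as.integer(max(nz))
  tibble(support_length = length(nz), first_nonzero = first, last_nonzero = last,
         center = as.integer((first + last) %/% 2L))
}

#' Volume length of a reagent mask
#'
#' The support length of the row projection: the number of vertical positions
#' at which the segmented reagent is present. Because the tip is conical, the
#' aspirated volume is proportional to the cube of this length, which is what
#' makes it usable as an image-derived volume estimate.
#'
#' @param mask A 0/1 matrix from the reagent segmentation chain.
#' @return Integer number of non-zero rows; 0 for an empty mask (empty tip).
#' @export
volume_length <- function(mask) {
  support_stats(row_profile(mask))$support_length
}

#' Tip position from a mask
#'
#' The support centre of the column projection. An empty mask yields `NA`,
#' the "tip absent" detection outcome.
#'
#' @param mask A 0/1 matrix of the tip region.
#' @return Integer column index, or `NA_integer_` when no tip is detected.
#' @export
tip_position <- function(mask) {
  support_stats(column_profile(mask))$center
}

#' Holder top position from a mask
#'
#' The upper limit (first non-zero row) of the row projection of a holder
#' mask. An empty mask yields `NA`, the "holder absent" outcome.
#'
#' @param mask A 0/1 matrix of the holder region.
#' @return Integer row index, or `NA_integer_` when no holder is detected.
#' @export
holder_top <- function(mask) {
  support_stats(row_profile(mask))$first_nonzero
}
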