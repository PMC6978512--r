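#' Bundle aligned forest-structure layers for one detection variant
#'
#' A `structure_grid` holds the pre-disturbance live forest structure used to
#' spread surveyed dead-tree counts across pixels: live tree density `tph`
#' (trees/ha), live aboveground biomass `bph` (BDT/ha) and live stem volume
#' `vph` (m^3/ha), all on one [grid_spec()]. The `variant` tag records which
#' tree-size subset the layers describe: `"dbh_ge_25cm"` (trees large enough
#' to be counted reliably from the air; drives the upper-bound estimate) or
#' `"dbh_ge_2p5cm"` (all trees; drives the lower bound).
#'
#' @param spec A [grid_spec()].
#' @param variant `"dbh_ge_25cm"` or `"dbh_ge_2p5cm"`.
#' @param tph,bph,vph Numeric matrices on `spec`'s grid; non-negative, with
#'   `bph`/`vph` positive only where `tph` is positive.
#' @param forest_mask Optional logical matrix; defaults to `tph > 0`.
#' @return An object of class `structure_grid`.
#' @export
structure_grid <- function(spec, variant = c("dbh_ge_25cm", "dbh_ge_2p5cm"),
                           tph, bph, vph, forest_mask = NULL) {
  variant <- match.arg(variant)
  for (nm in c("tph", "bph", "vph")) {
    m <- get(nm)
    stopifnot(is.matrix(m), nrow(m) == spec$n_rows, ncol(m) == spec$n_cols)
    if (any(m < 0, na.rm = TRUE)) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (any(bph > 0 & tph == 0)) stop("bph > 0 requires tph > 0", call. = FALSE)
  if (any(vph > 0 & tph == 0)) stop("vph > 0 requires tph > 0", call. = FALSE)
  if (is.null(forest_mask)) forest_mask <- tph > 0
  if (any((tph > 0 | bph > 0 | vph > 0) & !forest_mask)) {
    stop("non-forest pixels must have tph = bph = vph = 0", call. = FALSE)
  }
  structure(list(spec = spec, variant = variant, tph = tph, bph = bph,
                 vph = vph, forest_mask = forest_mask),
            class = "structure_grid")
}

#' @export
print.structure_grid <- function(x, ...) {
  cat(sprintf("<structure_grid> variant %s, %d x %d px, %d forested (%.1f%%)\n",
              x$variant, x$spec$n_rows, x$spec$n_cols, sum(x$forest_mask),
              100 * mean(x$forest_mask)))
  invisible(x)
}

#' Mean live stem volume per tree
#'
#' Pixel-level proxy for tree size used by the chipping-equipment filters:
#' `vpt = vph / tph` (m^3/tree) where live trees are present, and `NA` on
#' treeless pixels (those pixels carry no biomass and are excluded
#' downstream).
#'
#' @param structure A [structure_grid()].
#' @return Numeric matrix of mean tree volume (m^3), `NA` where `tph == 0`.
#' @export
mean_tree_volume <- function(structure) {
  vpt <- matrix(NA_real_, structure$spec$n_rows, structure$spec$n_cols)
  pos <- structure$tph > 0
  vpt[pos] <- structure$vph[pos] / structure$tph[pos]
  vpt
}
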