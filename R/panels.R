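#' Construct a marker panel
#'
#' Builds the marker subsets used for prediction at reduced density:
#' \describe{
#'   \item{WGS}{all markers.}
#'   \item{FUN1}{coding variants, eQTLs, variants in regulatory elements
#'     detected by ATAC-seq or epigenetic data, and MMD array markers.}
#'   \item{FUN2}{as FUN1 but regulatory evidence restricted to the ATAC-seq
#'     catalogue only.}
#'   \item{FUN3}{as FUN1 but regulatory evidence restricted to the
#'     epigenetic catalogue only.}
#'   \item{LD99 ... LD80}{LD pruning at r-squared thresholds 0.99, 0.98,
#'     0.95, 0.90, 0.80 (or any threshold via `ld_threshold`).}
#'   \item{ARRAY}{markers present on commercial genotyping arrays.}
#' }
#'
#' @param geno a `genotype_matrix`.
#' @param tracks a `feature_tracks` object (not needed for LD panels).
#' @param name panel name (`"WGS"`, `"FUN1"`, `"FUN2"`, `"FUN3"`,
#'   `"LD99"`, `"LD98"`, `"LD95"`, `"LD90"`, `"LD80"`, `"LD"`, `"ARRAY"`).
#' @param ld_threshold r-squared threshold for `name = "LD"`; the named LD
#'   panels imply their threshold.
#' @param window_bp pruning window for LD panels.
#' @return character vector of de-duplicated marker ids restricted to the
#'   genotyped set, in position order.
#' @export
build_panel <- function(geno, tracks = NULL, name, ld_threshold = NULL,
                        window_bp = 1e6) {
  meta <- geno$marker_meta
  ids <- meta$marker_id
  ld_named <- c(LD99 = 0.99, LD98 = 0.98, LD95 = 0.95, LD90 = 0.90,
                LD80 = 0.80)
  sel <- if (name == "WGS") {
    ids
  } else if (name %in% c("FUN1", "FUN2", "FUN3")) {
    if (is.null(tracks)) stop("tracks required for FUN panels")
    reg <- switch(name,
      FUN1 = overlaps_intervals(meta, tracks$atac) |
             overlaps_intervals(meta, tracks$epigenetic),
      FUN2 = overlaps_intervals(meta, tracks$atac),
      FUN3 = overlaps_intervals(meta, tracks$epigenetic))
    union(ids[reg],
          union(intersect(tracks$coding_ids, ids),
                union(intersect(tracks$eqtl$marker_id, ids),
                      intersect(tracks$mmd_ids, ids))))
  } else if (name %in% names(ld_named) || name == "LD") {
    thr <- if (name == "LD") ld_threshold else ld_named[[name]]
    if (is.null(thr)) stop("ld_threshold required for LD panel")
    ld_prune(geno, r2_threshold = thr, window_bp = window_bp)
  } else if (name == "ARRAY") {
    if (is.null(tracks)) stop("tracks required for ARRAY panel")
    intersect(tracks$array_ids, ids)
  } else if (name == "MMD") {
    if (is.null(tracks)) stop("tracks required for MMD panel")
    intersect(tracks$mmd_ids, ids)
  } else {
    stop("unknown panel name: ", name)
  }
  ids[ids %in% sel]  # position order, de-duplicated
}
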