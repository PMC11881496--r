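#' Annotation map: a partition of markers into functional groups
#'
#' @param assignments tibble with `marker_id` and `group`.
#' @param model_name one of `"FAN1"`, `"FAN2"`, `"LDMS"`, `"LDMSxFAN1"` or a
#'   custom label.
#' @param group_labels ordered vector of all group labels (empty groups are
#'   retained with size 0).
#' @return an object of class `annotation_map`.
#' @export
annotation_map <- function(assignments, model_name, group_labels) {
  assignments <- tibble::as_tibble(assignments)
  stopifnot(all(c("marker_id", "group") %in% names(assignments)))
  if (!all(assignments$group %in% group_labels)) {
    stop("assignments contain groups outside group_labels")
  }
  if (anyDuplicated(assignments$marker_id)) {
    stop("each marker must be assigned to exactly one group")
  }
  structure(list(assignments = assignments),
            model_name = model_name, group_labels = group_labels,
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  gs <- group_sizes(x)
  cat("<annotation_map> model =", attr(x, "model_name"), "|",
      nrow(x$assignments), "markers in", length(gs), "groups\n")
  print(gs)
  invisible(x)
}

#' Group sizes of an annotation map
#' @param anno an `annotation_map`
#' @return named integer vector over all group labels (including empty ones).
#' @export
group_sizes <- function(anno) {
  labs <- attr(anno, "group_labels")
  tab <- table(factor(anno$assignments$group, levels = labs))
  stats::setNames(as.integer(tab), labs)
}

fan1_labels <- c("coding", "eqtl", "reg_atac", "reg_epigenetic", "reg_both",
                 "exon_assoc", "intronic", "intergenic")
fan2_labels <- c("coding", "eqtl_muscle", "eqtl_other", "reg_muscle",
                 "reg_other", "exon_assoc", "intronic", "intergenic")

#' Functional annotation models FAN1 and FAN2
#'
#' Assigns every marker to exactly one group. When a marker qualifies for
#' several groups, the group with the highest expected effect wins; the
#' ranking is coding > eQTL > regulatory elements (ATAC-seq or epigenetic
#' evidence) > exon-associated > intronic > intergenic (the fallback).
#'
#' `assign_fan1` splits regulatory variants by evidence type into
#' `reg_both` (ATAC and epigenetic), `reg_epigenetic` (epigenetic only) and
#' `reg_atac` (ATAC only), giving eight groups. `assign_fan2` instead splits
#' eQTL and regulatory variants by tissue: groups detected in muscle versus
#' other tissues (muscle takes precedence when both kinds of evidence
#' overlap), also eight groups.
#'
#' @param geno a `genotype_matrix` (or a marker metadata data frame with
#'   `marker_id`, `chrom`, `pos`).
#' @param tracks a `feature_tracks` object.
#' @return an `annotation_map`.
#' @export
assign_fan1 <- function(geno, tracks) {
  meta <- .marker_meta_of(geno)
  in_atac <- overlaps_intervals(meta, tracks$atac)
  in_epi <- overlaps_intervals(meta, tracks$epigenetic)
  grp <- rep("intergenic", nrow(meta))
  grp[overlaps_intervals(meta, tracks$intron)] <- "intronic"
  grp[overlaps_intervals(meta, tracks$exon_assoc)] <- "exon_assoc"
  grp[in_atac & !in_epi] <- "reg_atac"
  grp[in_epi & !in_atac] <- "reg_epigenetic"
  grp[in_atac & in_epi] <- "reg_both"
  grp[meta$marker_id %in% tracks$eqtl$marker_id] <- "eqtl"
  grp[meta$marker_id %in% tracks$coding_ids] <- "coding"
  annotation_map(tibble::tibble(marker_id = meta$marker_id, group = grp),
                 "FAN1", fan1_labels)
}

#' @rdname assign_fan1
#' @export
assign_fan2 <- function(geno, tracks) {
  meta <- .marker_meta_of(geno)
  in_atac <- overlaps_intervals(meta, tracks$atac)
  epi_muscle <- tracks$epigenetic[tracks$epigenetic$muscle, , drop = FALSE]
  in_epi_any <- overlaps_intervals(meta, tracks$epigenetic)
  in_muscle_iv <- overlaps_intervals(meta, epi_muscle)
  if ("muscle" %in% names(tracks$atac)) {
    in_muscle_iv <- in_muscle_iv |
      overlaps_intervals(meta, tracks$atac[tracks$atac$muscle, , drop = FALSE])
  }
  reg <- in_atac | in_epi_any
  grp <- rep("intergenic", nrow(meta))
  grp[overlaps_intervals(meta, tracks$intron)] <- "intronic"
  grp[overlaps_intervals(meta, tracks$exon_assoc)] <- "exon_assoc"
  grp[reg & !in_muscle_iv] <- "reg_other"
  grp[reg & in_muscle_iv] <- "reg_muscle"
  is_eqtl <- meta$marker_id %in% tracks$eqtl$marker_id
  muscle_eqtl <- meta$marker_id %in%
    tracks$eqtl$marker_id[tracks$eqtl$muscle]
  grp[is_eqtl & !muscle_eqtl] <- "eqtl_other"
  grp[muscle_eqtl] <- "eqtl_muscle"
  grp[meta$marker_id %in% tracks$coding_ids] <- "coding"
  annotation_map(tibble::tibble(marker_id = meta$marker_id, group = grp),
                 "FAN2", fan2_labels)
}

.marker_meta_of <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno$marker_meta
  else tibble::as_tibble(geno)
}

#' LD/MAF stratification (LDMS)
#'
#' Twelve groups from the cross of three MAF bins -- (0.01, 0.05],
#' (0.05, 0.10], (0.10, 0.50] -- and four LD-score quartile bins. Quartile
#' boundaries use the nearest-rank quantile of the LD scores of the marker
#' set being grouped; a score exactly on a boundary goes to the lower
#' quartile. Markers with MAF at or below 0.01 fall into the lowest bin.
#'
#' @param geno a `genotype_matrix`.
#' @param ld tibble from [ld_scores()] covering all markers (computed if
#'   `NULL`).
#' @param window_bp LD-score window when `ld` must be computed.
#' @return an `annotation_map` with groups `MS{1..3}_LD{1..4}`.
#' @export
build_ldms <- function(geno, ld = NULL, window_bp = 1e6) {
  if (is.null(ld)) ld <- ld_scores(geno, window_bp)
  sc <- ld$ld_score[match(geno$marker_meta$marker_id, ld$marker_id)]
  if (anyNA(sc)) stop("LD scores missing for some markers")
  if (length(unique(sc)) < 4) {
    stop("fewer than 4 distinct LD scores; quartile binning is degenerate")
  }
  qs <- stats::quantile(sc, c(0.25, 0.5, 0.75), type = 1)  # nearest rank
  ld_bin <- findInterval(sc, qs, left.open = TRUE) + 1L    # boundary -> lower
  m <- maf(geno)
  ms_bin <- cut(m, breaks = c(-Inf, 0.05, 0.10, 0.50),
                labels = FALSE, right = TRUE)
  grp <- paste0("MS", ms_bin, "_LD", ld_bin)
  labs <- as.vector(t(outer(paste0("MS", 1:3), paste0("_LD", 1:4), paste0)))
  annotation_map(tibble::tibble(marker_id = geno$marker_meta$marker_id,
                                group = grp), "LDMS", labs)
}

#' Cross two annotation maps
#'
#' Cartesian product of two partitions over the same markers (e.g.
#' LDMS x FAN1 gives 12 x 8 = 96 groups). Empty cells are retained with
#' size 0.
#'
#' @param a,b `annotation_map`s over the same markers.
#' @return an `annotation_map` with labels `<a group>.<b group>`.
#' @export
cross_groups <- function(a, b) {
  am <- a$assignments
  bm <- b$assignments
  j <- match(am$marker_id, bm$marker_id)
  if (anyNA(j)) stop("annotation maps cover different marker sets")
  grp <- paste(am$group, bm$group[j], sep = ".")
  labs <- as.vector(outer(attr(a, "group_labels"), attr(b, "group_labels"),
                          paste, sep = "."))
  annotation_map(tibble::tibble(marker_id = am$marker_id, group = grp),
                 paste0(attr(a, "model_name"), "x", attr(b, "model_name")),
                 labs)
}
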