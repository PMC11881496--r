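#' Functional feature tracks
#'
#' Container for the annotation evidence used to classify markers:
#' variant-level sets (coding consequences, cis-eQTL lead variants with a
#' muscle flag, medium-density and commercial array memberships) and
#' interval tracks (open-chromatin peaks from ATAC-seq, active chromatin
#' states from epigenetic data with a muscle flag, exon-associated regions
#' -- exons, UTRs and 1 kb up/downstream of TSS/TTS -- and introns).
#' Intervals are stored 1-based closed and sorted per chromosome.
#'
#' @param coding_ids character vector of protein-altering variant ids.
#' @param eqtl tibble `marker_id`, `muscle` (logical).
#' @param atac intervals tibble `chrom`, `start`, `end`.
#' @param epigenetic intervals tibble `chrom`, `start`, `end`, `muscle`.
#' @param exon_assoc,intron intervals tibbles `chrom`, `start`, `end`.
#' @param mmd_ids,array_ids character vectors of array marker ids.
#' @return an object of class `feature_tracks`.
#' @export
feature_tracks <- function(coding_ids = character(),
                           eqtl = tibble::tibble(marker_id = character(),
                                                 muscle = logical()),
                           atac = empty_intervals(),
                           epigenetic = empty_intervals(muscle = TRUE),
                           exon_assoc = empty_intervals(),
                           intron = empty_intervals(),
                           mmd_ids = character(),
                           array_ids = character()) {
  eqtl <- tibble::as_tibble(eqtl)
  if (!"muscle" %in% names(eqtl)) eqtl$muscle <- FALSE
  norm_iv <- function(x, need_muscle = FALSE) {
    x <- tibble::as_tibble(x)
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (need_muscle && !"muscle" %in% names(x)) x$muscle <- FALSE
    x$chrom <- as.character(x$chrom)
    dplyr::arrange(x, .data$chrom, .data$start)
  }
  structure(list(coding_ids = unique(as.character(coding_ids)),
                 eqtl = dplyr::distinct(eqtl),
                 atac = norm_iv(atac),
                 epigenetic = norm_iv(epigenetic, need_muscle = TRUE),
                 exon_assoc = norm_iv(exon_assoc),
                 intron = norm_iv(intron),
                 mmd_ids = unique(as.character(mmd_ids)),
                 array_ids = unique(as.character(array_ids))),
            class = "feature_tracks")
}

empty_intervals <- function(muscle = FALSE) {
  x <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  if (muscle) x$muscle <- logical()
  x
}

#' @export
print.feature_tracks <- function(x, ...) {
  cat("<feature_tracks> coding:", length(x$coding_ids),
      "| eQTL:", nrow(x$eqtl),
      "| ATAC ivs:", nrow(x$atac),
      "| epigenetic ivs:", nrow(x$epigenetic),
      "| exon-assoc ivs:", nrow(x$exon_assoc),
      "| intron ivs:", nrow(x$intron),
      "| MMD:", length(x$mmd_ids),
      "| ARRAY:", length(x$array_ids), "\n")
  invisible(x)
}

# TRUE for each marker whose 1-based position lies inside any interval
# (indels judged by start position only, i.e. by `pos` itself).
overlaps_intervals <- function(meta, intervals) {
  hit <- logical(nrow(meta))
  if (!nrow(intervals)) return(hit)
  for (chr in unique(meta$chrom)) {
    mi <- which(meta$chrom == chr)
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    if (!nrow(iv)) next
    q <- IRanges::IRanges(start = meta$pos[mi], width = 1L)
    s <- IRanges::IRanges(start = iv$start, end = iv$end)
    hit[mi] <- IRanges::overlapsAny(q, s)
  }
  hit
}
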