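#' Read a plain dosage matrix
#'
#' TSV with header `marker_id chrom pos ref alt <sample ids...>`, one marker
#' per row; dosage cells in `[0, 2]`, `NA` allowed.
#'
#' @param path file path.
#' @return a `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("marker_id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(d))) {
    stop("dosage TSV must start with columns: ", paste(meta_cols, collapse = " "))
  }
  samp <- setdiff(names(d), meta_cols)
  dos <- t(as.matrix(d[, samp, drop = FALSE]))
  meta <- tibble::as_tibble(d[, meta_cols])
  meta$chrom <- as.character(meta$chrom)
  genotype_matrix(dos, meta, sample_ids = samp)
}

#' Write a plain dosage matrix
#' @param geno a `genotype_matrix`
#' @param path output file path.
#' @param digits dosage rounding for output.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path, digits = 4) {
  d <- cbind(geno$marker_meta[, c("marker_id", "chrom", "pos", "ref", "alt")],
             as.data.frame(t(round(geno$dosages, digits))))
  names(d)[-(1:5)] <- geno$sample_ids
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bi-allelic dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise falls back to hard
#' genotype calls from `GT`. Multi-allelic records are dropped.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  fmt <- unique(v@gt[, "FORMAT"])
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(g) {
      a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
      vapply(a, function(x) {
        x <- suppressWarnings(as.numeric(x))
        if (anyNA(x)) NA_real_ else sum(x)
      }, numeric(1))
    })
    ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  ds <- ds[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  meta <- tibble::tibble(marker_id = id, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"])
  genotype_matrix(t(ds), meta, sample_ids = colnames(ds))
}

#' Read a phenotype table
#'
#' TSV with columns `sample_id` and one column per trait (pre-corrected
#' trait deviations). An optional `birth_date` column (ISO dates) is parsed
#' for reference/target splitting.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_phenotypes_tsv <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(d)) stop("phenotype TSV needs a sample_id column")
  if ("birth_date" %in% names(d)) d$birth_date <- as.Date(d$birth_date)
  d
}

#' Read a BED interval track
#'
#' BED is 0-based half-open; intervals are converted to 1-based closed
#' `[start + 1, end]` internally.
#'
#' @param path BED file (first three columns chrom/start/end; an optional
#'   4th column equal to `muscle` or `1` marks muscle intervals).
#' @return tibble with `chrom`, `start`, `end`, `muscle`.
#' @export
read_bed_track <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- tibble::tibble(chrom = as.character(d[[1]]),
                        start = as.integer(d[[2]]) + 1L,
                        end = as.integer(d[[3]]),
                        muscle = FALSE)
  if (ncol(d) >= 4) out$muscle <- d[[4]] %in% c("muscle", "1", 1, TRUE)
  out
}

#' Read a newline-delimited marker id list
#'
#' @param path text file; either one id per line, or two tab-separated
#'   columns where the second (`muscle`/`1`) flags muscle evidence.
#' @return tibble with `marker_id`, `muscle`.
#' @export
read_id_list <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- tibble::tibble(marker_id = as.character(d[[1]]), muscle = FALSE)
  if (ncol(d) >= 2) out$muscle <- d[[2]] %in% c("muscle", "1", 1, TRUE)
  out
}
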