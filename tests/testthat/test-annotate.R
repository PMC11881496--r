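# A small deterministic marker set + tracks exercising every rule.
make_meta <- function(n, chrom = "1") {
  tibble::tibble(marker_id = paste0("v", seq_len(n)), chrom = chrom,
                 pos = seq_len(n) * 100L, ref = "A", alt = "B")
}

test_that("FAN1 resolves multiple annotations by the effect hierarchy", {
  meta <- make_meta(6)
  tracks <- feature_tracks(
    coding_ids = "v1",
    eqtl = tibble::tibble(marker_id = "v2", muscle = TRUE),
    atac = tibble::tibble(chrom = "1", start = c(95L, 295L, 395L),
                          end = c(105L, 305L, 405L)),
    epigenetic = tibble::tibble(chrom = "1", start = c(295L, 495L),
                                end = c(305L, 505L), muscle = FALSE),
    exon_assoc = tibble::tibble(chrom = "1", start = 195L, end = 600L))
  a <- assign_fan1(meta, tracks)
  got <- setNames(a$assignments$group, a$assignments$marker_id)
  expect_equal(unname(got["v1"]), "coding")        # coding beats ATAC overlap
  expect_equal(unname(got["v2"]), "eqtl")
  expect_equal(unname(got["v3"]), "reg_both")      # ATAC + epigenetic
  expect_equal(unname(got["v4"]), "reg_atac")
  expect_equal(unname(got["v5"]), "reg_epigenetic")
  expect_equal(unname(got["v6"]), "exon_assoc")    # regulatory beats exon_assoc
})

test_that("unannotated markers fall back to intergenic", {
  meta <- make_meta(3)
  a <- assign_fan1(meta, feature_tracks())
  expect_true(all(a$assignments$group == "intergenic"))
  expect_equal(sum(group_sizes(a)), 3L)
})

test_that("FAN2 separates muscle evidence with muscle precedence", {
  meta <- make_meta(5)
  tracks <- feature_tracks(
    coding_ids = "v4",
    eqtl = tibble::tibble(marker_id = c("v1", "v2", "v4"),
                          muscle = c(TRUE, FALSE, TRUE)),
    atac = tibble::tibble(chrom = "1", start = 295L, end = 305L),
    epigenetic = tibble::tibble(chrom = "1", start = c(295L, 495L),
                                end = c(305L, 505L),
                                muscle = c(TRUE, FALSE)))
  a <- assign_fan2(meta, tracks)
  got <- setNames(a$assignments$group, a$assignments$marker_id)
  expect_equal(unname(got["v1"]), "eqtl_muscle")
  expect_equal(unname(got["v2"]), "eqtl_other")
  # v3 overlaps a muscle epigenetic interval AND a non-muscle ATAC peak
  expect_equal(unname(got["v3"]), "reg_muscle")
  expect_equal(unname(got["v4"]), "coding")        # coding beats muscle eQTL
  expect_equal(unname(got["v5"]), "reg_other")
})

test_that("assignments are a partition and invariant to track row order", {
  dat <- small_sim(n = 50, M = 800, seed = 77)
  a1 <- assign_fan1(dat$geno, dat$tracks)
  expect_equal(sum(group_sizes(a1)), n_markers(dat$geno))
  shuffle <- function(x) x[sample.int(nrow(x)), , drop = FALSE]
  set.seed(1)
  tr2 <- feature_tracks(
    coding_ids = sample(dat$tracks$coding_ids),
    eqtl = shuffle(dat$tracks$eqtl),
    atac = shuffle(dat$tracks$atac),
    epigenetic = shuffle(dat$tracks$epigenetic),
    exon_assoc = shuffle(dat$tracks$exon_assoc),
    intron = shuffle(dat$tracks$intron),
    mmd_ids = sample(dat$tracks$mmd_ids),
    array_ids = sample(dat$tracks$array_ids))
  a2 <- assign_fan1(dat$geno, tr2)
  expect_identical(a1$assignments, a2$assignments)
  a3 <- assign_fan2(dat$geno, dat$tracks)
  a4 <- assign_fan2(dat$geno, tr2)
  expect_identical(a3$assignments, a4$assignments)
})

test_that("LDMS builds 12 MAF-by-LD-quartile groups deterministically", {
  dat <- small_sim(n = 200, M = 2000, seed = 55)
  sc <- ld_scores(dat$geno)
  ldms <- build_ldms(dat$geno, sc)
  sizes <- group_sizes(ldms)
  expect_length(sizes, 12L)
  expect_equal(sum(sizes), 2000L)
  # quartile bins hold ~25% each (nearest-rank boundaries, ties to lower)
  ld_tot <- tapply(sizes, sub("^MS._", "", names(sizes)), sum)
  expect_true(all(abs(ld_tot - 500) <= 0.02 * 2000))
  # MAF bin membership: a marker with MAF in (0.05, 0.10] gets MS2
  m <- maf(dat$geno)
  j <- which(m > 0.05 & m <= 0.10)[1]
  got <- ldms$assignments$group[ldms$assignments$marker_id ==
                                  dat$geno$marker_meta$marker_id[j]]
  expect_match(got, "^MS2_")

  # degenerate LD scores -> error
  sc0 <- sc
  sc0$ld_score <- 1
  expect_error(build_ldms(dat$geno, sc0), "distinct")
})

test_that("crossing LDMS and FAN1 yields the 96-cell partition", {
  dat <- small_sim(n = 100, M = 1200, seed = 66)
  fan <- assign_fan1(dat$geno, dat$tracks)
  ldms <- build_ldms(dat$geno)
  x <- cross_groups(ldms, fan)
  expect_length(attr(x, "group_labels"), 96L)
  expect_equal(sum(group_sizes(x)), 1200L)  # empty cells kept at size 0
  # spot-check one marker's pair
  mid <- dat$geno$marker_meta$marker_id[1]
  gl <- ldms$assignments$group[ldms$assignments$marker_id == mid]
  gf <- fan$assignments$group[fan$assignments$marker_id == mid]
  expect_equal(x$assignments$group[x$assignments$marker_id == mid],
               paste(gl, gf, sep = "."))
})

test_that("FUN panels are unions per rule, FUN2/FUN3 nested in FUN1", {
  meta <- make_meta(25)
  g <- toy_geno(matrix(rbinom(10 * 25, 2, 0.3), 10), pos = meta$pos)
  g$marker_meta$marker_id <- meta$marker_id
  colnames(g$dosages) <- meta$marker_id
  pos_of <- function(ids) meta$pos[match(ids, meta$marker_id)]
  # 5 coding, 3 eQTL, 10 regulatory (6 ATAC + 4 epigenetic), 4 MMD with one
  # overlapping a coding id -> |union| = 5 + 3 + 10 + 3 = 21
  tracks <- feature_tracks(
    coding_ids = paste0("v", 1:5),
    eqtl = tibble::tibble(marker_id = paste0("v", 6:8), muscle = FALSE),
    atac = tibble::tibble(chrom = "1", start = pos_of(paste0("v", 9:14)),
                          end = pos_of(paste0("v", 9:14))),
    epigenetic = tibble::tibble(chrom = "1",
                                start = pos_of(paste0("v", 15:18)),
                                end = pos_of(paste0("v", 15:18)),
                                muscle = FALSE),
    mmd_ids = c("v1", paste0("v", 19:21)))
  fun1 <- build_panel(g, tracks, "FUN1")
  expect_length(fun1, 21L)
  fun2 <- build_panel(g, tracks, "FUN2")
  fun3 <- build_panel(g, tracks, "FUN3")
  expect_true(all(fun2 %in% fun1))
  expect_true(all(fun3 %in% fun1))
  # FUN3 drops ATAC-only regulatory markers present in FUN1
  expect_false(any(paste0("v", 9:14) %in% fun3))
  expect_true(all(paste0("v", 15:18) %in% fun3))
  expect_error(build_panel(g, tracks, "FOO"), "unknown panel")
})

test_that("panel nesting holds on simulated tracks", {
  dat <- small_sim(n = 80, M = 1500, seed = 88)
  fun1 <- build_panel(dat$geno, dat$tracks, "FUN1")
  fun2 <- build_panel(dat$geno, dat$tracks, "FUN2")
  fun3 <- build_panel(dat$geno, dat$tracks, "FUN3")
  expect_true(all(fun2 %in% fun1) && all(fun3 %in% fun1))
  arr <- build_panel(dat$geno, dat$tracks, "ARRAY")
  expect_true(all(build_panel(dat$geno, dat$tracks, "MMD") %in% arr))
  expect_identical(build_panel(dat$geno, dat$tracks, "WGS"),
                   dat$geno$marker_meta$marker_id)
})
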