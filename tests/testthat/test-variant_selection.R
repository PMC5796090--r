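# Curation rules, frequency arithmetic, ranking.

test_that("protein-change parsing handles both dialects", {
  p <- parse_protein_change(c("p.Thr93Met", "T93M", "p.Arg404Cys"))
  expect_equal(p$id, c("T93M", "T93M", "R404C"))
  expect_equal(p$position, c(93L, 93L, 404L))
  expect_error(parse_protein_change("T93"), "cannot parse")
  expect_error(parse_protein_change("T93T"), "equal")
  expect_error(parse_protein_change("X93M"), "unknown residue")
})

test_that("ClinVar branch: labels, af gate, override list", {
  d <- memtriage:::validate_variant_records(toy_variant_table())
  out <- classify_by_curation(d)
  # R352W fails the af gate (1e-6), G410S benign is dropped
  expect_false("R352W" %in% out$id)
  expect_false("G410S" %in% out$id)
  expect_setequal(out$id[out$label == "pathogenic"],
                  c("T93M", "R404C", "E288K", "L99P"))  # E288K forced
  expect_setequal(out$id[out$label == "unknown"], c("V126I", "A41V"))

  # without the override E288K stays unknown
  out2 <- classify_by_curation(d, override = character(0))
  expect_identical(out2$label[out2$id == "E288K"], "unknown")

  # boundary: af exactly at the gate is excluded (strict >)
  d2 <- d; d2$af_exac[d2$id == "T93M"] <- 1e-5
  expect_false("T93M" %in% classify_by_curation(d2)$id)

  # idempotence
  expect_identical(classify_by_curation(d)[names(out)],
                   classify_by_curation(classify_by_curation(d))[names(out)])

  # unrecognized significance names the row
  bad <- toy_variant_table()
  bad$clinical_significance[3] <- "totally_new"
  expect_error(memtriage:::validate_variant_records(bad), "row 3")
})

test_that("population branch: 1000G>0 AND ESP==0, exactly", {
  d <- memtriage:::validate_variant_records(toy_variant_table())
  out <- select_nonpathogenic(d)
  brute <- d$id[d$af_1000g > 0 & d$af_esp == 0]
  expect_setequal(out$id, brute)
  expect_true(all(out$label == "non_pathogenic"))

  # degenerate: no 1000G carriers anywhere
  d0 <- d; d0$af_1000g <- 0
  expect_equal(nrow(select_nonpathogenic(d0)), 0L)
  d1 <- d; d1$af_esp <- 1e-4
  expect_equal(nrow(select_nonpathogenic(d1)), 0L)

  # disjoint from the curation branch on this table
  expect_length(intersect(classify_by_curation(d)$id[
    classify_by_curation(d)$label == "pathogenic"], out$id), 0)
})

test_that("sex frequencies are fractions of carriers summing to 1", {
  expect_equal(sex_frequency(list(n_female = 3, n_male = 1)),
               c(female_fraction = 0.75, male_fraction = 0.25))
  expect_equal(sex_frequency(list(n_female = 0, n_male = 5)),
               c(female_fraction = 0, male_fraction = 1))
  d <- memtriage:::validate_variant_records(toy_variant_table())
  for (i in seq_len(nrow(d))) {
    expect_equal(sum(sex_frequency(d[i, ])), 1)
  }
  expect_error(sex_frequency(list(n_female = 0, n_male = 0)), "undefined")
})

test_that("top_frequent matches an oracle sort with deterministic ties", {
  set.seed(31)
  n <- 100
  d <- data.frame(
    protein_change = sprintf("%s%d%s", sample(AA_ONE, n, TRUE), 1:n,
                             sample(AA_ONE, n, TRUE)),
    clinical_significance = "uncertain",
    af_exac = sample(c(1e-4, 2e-4, 5e-4, 1e-3), n, TRUE),
    af_1000g = 0, af_esp = 0,
    n_female = sample(0:200, n, TRUE), n_male = sample(0:200, n, TRUE),
    stringsAsFactors = FALSE)
  d$protein_change <- ifelse(
    substr(d$protein_change, 1, 1) ==
      substr(d$protein_change, nchar(d$protein_change),
             nchar(d$protein_change)),
    paste0("T", 1:n, "M"), d$protein_change)
  r <- memtriage:::validate_variant_records(d)
  out <- top_frequent(r, min_individuals = 50, k = 40)
  surv <- r[(r$n_female + r$n_male) > 50, ]
  orc <- surv[order(-surv$af_exac, surv$position, surv$alt), ][
    seq_len(min(40, nrow(surv))), ]
  expect_equal(out$id, orc$id)
  # k larger than survivors returns all; min_individuals=0 is a pure top-k
  expect_equal(nrow(top_frequent(r, 1e9, 40)), 0L)
  expect_equal(nrow(top_frequent(r, 0, 1e6)), nrow(r))
})

test_that("TSV and VCF readers enforce the header contract", {
  f <- tempfile(fileext = ".tsv")
  write_variant_table(toy_variant_table(), f)
  d <- read_variant_table(f)
  expect_equal(nrow(d), 8L)
  expect_true(all(c("ref", "position", "alt", "id") %in% names(d)))

  # missing frequency column is a hard error
  broken <- toy_variant_table(); broken$af_esp <- NULL
  f2 <- tempfile(fileext = ".tsv")
  write_variant_table(broken, f2)
  expect_error(read_variant_table(f2), "af_esp")

  # missing (NA) frequency is an error; explicit 0 is data
  na_tab <- toy_variant_table(); na_tab$af_1000g[2] <- NA
  f3 <- tempfile(fileext = ".tsv")
  write_variant_table(na_tab, f3)
  expect_error(read_variant_table(f3), "af_1000g")

  # VCF secondary path
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           paste0("11\t100\t.\tC\tT\t.\tPASS\t",
                  "CSQ_PCHANGE=p.Thr93Met;CLNSIG=pathogenic;AF_EXAC=0.001;",
                  "AF_1000G=0;AF_ESP=0.001;N_FEMALE=30;N_MALE=25"))
  fv <- tempfile(fileext = ".vcf")
  writeLines(vcf, fv)
  dv <- read_variant_vcf(fv)
  expect_equal(dv$id, "T93M")
  expect_equal(dv$af_exac, 0.001)
})
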