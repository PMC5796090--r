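# Curation of pathogenic / non-pathogenic / unknown missense variant sets
# from ClinVar/ExAC-style tables, plus population and sex frequency
# summaries.
#
# Two independent curation branches:
#   * the ClinVar-derived branch labels records by review significance
#     (pathogenic + likely_pathogenic -> pathogenic; uncertain -> unknown)
#     after an ExAC allele-frequency gate af_exac > 1e-5, with a literature
#     override list that forces specific protein changes to pathogenic;
#   * the population branch selects non-pathogenic records seen in the
#     healthy 1000 Genomes cohort (af_1000g > 0) but absent from the
#     disease-focused ESP cohort (af_esp == 0).

CLINICAL_SIGNIFICANCE <- c("benign", "likely_benign", "uncertain",
                           "likely_pathogenic", "pathogenic", "conflicting")

POPULATION_CODES <- c("AFR", "AMR", "EAS", "FIN", "NFE", "SAS", "OTH")

#' Parse protein-change notation
#'
#' Accepts both the HGVS-style three-letter dialect ("p.Thr93Met") and the
#' compact one-letter dialect ("T93M"); the internal form is one-letter,
#' 1-based.
#'
#' @param x character vector of protein changes.
#' @return data.frame with columns `ref` (one-letter), `position`, `alt`,
#'   and `id` (the normalized "T93M" form).
#' @examples
#' parse_protein_change(c("p.Thr93Met", "R404C"))
#' @export
parse_protein_change <- function(x) {
  out <- lapply(x, function(s) {
    s0 <- trimws(s)
    s1 <- sub("^p\\.", "", s0)
    m3 <- regmatches(s1, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", s1))[[1]]
    if (length(m3) == 4L) {
      ref <- aa_three_to_one(m3[2]); alt <- aa_three_to_one(m3[4])
      pos <- as.integer(m3[3])
    } else {
      m1 <- regmatches(s1, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s1))[[1]]
      check_that(length(m1) == 4L, "cannot parse protein change '%s'", s)
      ref <- toupper(m1[2]); alt <- toupper(m1[4]); pos <- as.integer(m1[3])
      check_that(ref %in% AA_ONE && alt %in% AA_ONE,
                 "unknown residue in protein change '%s'", s)
    }
    check_that(pos >= 1L, "position must be >= 1 in '%s'", s)
    check_that(ref != alt, "reference and alternate residues equal in '%s'", s)
    data.frame(ref = ref, position = pos, alt = alt,
               id = paste0(ref, pos, alt), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a ClinVar/ExAC-style variant table
#'
#' Tab-separated with a documented header contract; column names can be
#' remapped through `columns`. Required columns: `protein_change`,
#' `clinical_significance`, `af_exac`, `af_1000g`, `af_esp`, `n_female`,
#' `n_male`; per-population frequency columns `af_AFR` ... `af_OTH` are
#' optional. Frequencies must be present: an empty cell is an error, a 0
#' is data (the ESP criterion depends on true zeros).
#'
#' @param path path to the TSV.
#' @param columns named character vector mapping required names to the
#'   file's actual column names, e.g. `c(af_exac = "ExAC_AF")`.
#' @return data.frame of `MutationRecord` rows with parsed protein change
#'   columns (`ref`, `position`, `alt`, `id`) prepended.
#' @export
read_variant_table <- function(path, columns = NULL) {
  d <- read_tsv(path)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      check_that(columns[[std]] %in% names(d),
                 "column '%s' (mapped to %s) missing from %s",
                 columns[[std]], std, path)
      names(d)[names(d) == columns[[std]]] <- std
    }
  }
  need <- c("protein_change", "clinical_significance",
            "af_exac", "af_1000g", "af_esp", "n_female", "n_male")
  miss <- setdiff(need, names(d))
  check_that(length(miss) == 0L, "missing required columns in %s: %s",
             path, paste(miss, collapse = ", "))
  validate_variant_records(d)
}

#' Validate and normalize mutation records
#' @noRd
validate_variant_records <- function(d) {
  pc <- parse_protein_change(d$protein_change)
  d$clinical_significance <- tolower(trimws(d$clinical_significance))
  bad <- which(!(d$clinical_significance %in% CLINICAL_SIGNIFICANCE))
  if (length(bad)) {
    abort("unrecognized clinical significance '%s' in row %d (%s)",
          d$clinical_significance[bad[1]], bad[1], d$protein_change[bad[1]])
  }
  for (col in c("af_exac", "af_1000g", "af_esp")) {
    check_that(!anyNA(d[[col]]),
               "missing values in frequency column '%s' (0 must be explicit)",
               col)
    check_that(is_prob(d[[col]]), "column '%s' must lie in [0,1]", col)
  }
  cbind(pc, d[setdiff(names(d), names(pc))])
}

#' Read variant records from a VCF with a CSQ-style protein change
#'
#' Secondary input path: a VCF whose INFO field carries
#' `key=<protein change>` annotations (default key "CSQ_PCHANGE") plus the
#' same frequency/significance keys used by the TSV contract.
#'
#' @param path VCF path (uncompressed).
#' @param pchange_key INFO key holding the protein change.
#' @return data.frame as from [read_variant_table()].
#' @export
read_variant_vcf <- function(path, pchange_key = "CSQ_PCHANGE") {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  check_that(length(body) > 0L, "no variant records in %s", path)
  info <- vapply(strsplit(body, "\t"), function(f) f[[8]], "")
  get_key <- function(key) {
    vapply(strsplit(info, ";"), function(kv) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit)) sub("^[^=]*=", "", hit[[1]]) else NA_character_
    }, "")
  }
  d <- data.frame(
    protein_change = get_key(pchange_key),
    clinical_significance = get_key("CLNSIG"),
    af_exac = as.numeric(get_key("AF_EXAC")),
    af_1000g = as.numeric(get_key("AF_1000G")),
    af_esp = as.numeric(get_key("AF_ESP")),
    n_female = as.integer(get_key("N_FEMALE")),
    n_male = as.integer(get_key("N_MALE")),
    stringsAsFactors = FALSE)
  check_that(!anyNA(d$protein_change),
             "INFO key %s absent from some records in %s", pchange_key, path)
  validate_variant_records(d)
}

#' ClinVar-branch curation: pathogenic and unknown sets
#'
#' Rules: records must pass the ExAC allele-frequency gate
#' (af_exac > `af_gate`, default 1e-5); significance pathogenic or
#' likely_pathogenic labels a record pathogenic; uncertain labels it
#' unknown; benign, likely_benign and conflicting records are dropped.
#' Protein changes on the override list (default E288K and G303R, two
#' literature-confirmed disease mutations not curated as pathogenic) are
#' forced to pathogenic regardless of their significance.
#'
#' @param records data.frame from [read_variant_table()].
#' @param af_gate ExAC allele-frequency gate (strict >).
#' @param override protein changes (normalized one-letter ids) forced
#'   pathogenic.
#' @return the surviving records with a `label` column in
#'   {"pathogenic", "unknown"}.
#' @export
classify_by_curation <- function(records, af_gate = 1e-5,
                                 override = c("E288K", "G303R")) {
  check_that(all(records$clinical_significance %in% CLINICAL_SIGNIFICANCE),
             "records carry unvalidated significance values")
  r <- records[records$af_exac > af_gate, , drop = FALSE]
  label <- rep(NA_character_, nrow(r))
  label[r$clinical_significance %in% c("pathogenic", "likely_pathogenic")] <-
    "pathogenic"
  label[r$clinical_significance == "uncertain"] <- "unknown"
  label[r$id %in% override] <- "pathogenic"
  out <- r[!is.na(label), , drop = FALSE]
  out$label <- label[!is.na(label)]
  rownames(out) <- NULL
  out
}

#' Population-branch curation: non-pathogenic set
#'
#' Selects exactly the records observed in the healthy 1000 Genomes
#' cohort but absent from the ESP cohort: af_1000g > 0 AND af_esp == 0.
#'
#' @param records data.frame from [read_variant_table()].
#' @return the selected records with `label` set to "non_pathogenic".
#' @export
select_nonpathogenic <- function(records) {
  for (col in c("af_1000g", "af_esp")) {
    check_that(col %in% names(records), "missing frequency column '%s'", col)
    check_that(!anyNA(records[[col]]), "missing values in '%s'", col)
  }
  out <- records[records$af_1000g > 0 & records$af_esp == 0, , drop = FALSE]
  if (nrow(out)) out$label <- "non_pathogenic"
  rownames(out) <- NULL
  out
}

#' Carrier sex fractions for one record
#'
#' Fraction of carrier individuals that are female / male.
#'
#' @param record one mutation record (list or single data.frame row) with
#'   `n_female` and `n_male` carrier counts.
#' @return named numeric c(female_fraction, male_fraction), summing to 1.
#' @export
sex_frequency <- function(record) {
  nf <- record$n_female
  nm <- record$n_male
  check_that(is.numeric(nf) && is.numeric(nm) && nf >= 0 && nm >= 0,
             "carrier counts must be non-negative numbers")
  total <- nf + nm
  check_that(total > 0,
             "sex frequency undefined: record has zero carrier individuals")
  c(female_fraction = nf / total, male_fraction = nm / total)
}

#' Top-k most frequent mutations above a carrier-count floor
#'
#' Filters to records with carrier total (n_female + n_male) strictly
#' greater than `min_individuals`, sorts by overall ExAC allele frequency
#' descending (ties broken by position, then alternate residue, so the
#' ranking is deterministic), and returns the first `k`.
#'
#' @param records data.frame from [read_variant_table()].
#' @param min_individuals carrier-count floor (strict >; default 50).
#' @param k number of records to return (default 40).
#' @return ranked data.frame (possibly fewer than `k` rows).
#' @export
top_frequent <- function(records, min_individuals = 50, k = 40) {
  r <- records[(records$n_female + records$n_male) > min_individuals, ,
               drop = FALSE]
  ord <- order(-r$af_exac, r$position, r$alt)
  out <- r[ord[seq_len(min(k, nrow(r)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a curated variant set as TSV
#' @param records curated data.frame.
#' @param path output path.
#' @export
write_variant_table <- function(records, path) write_tsv(records, path)
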