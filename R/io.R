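#' Read a VCF into a genotype matrix
#'
#' Reads a biallelic VCF (4.x) and converts it to additive dosages. When a
#' `DS` FORMAT field is present it takes priority over `GT` (the convention
#' for imputed data); otherwise dosages are allele counts from `GT`. Missing
#' genotypes (`./.` with no `DS`) become missing dosages.
#'
#' @param path path to an uncompressed or bgzipped VCF file.
#' @param counted_allele which allele to count: `"alt"` (default) or `"ref"`.
#' @return A [genotype_matrix()]. Variant metadata carries the counted allele
#'   as `a1`, the other as `a2`, and the `INFO` imputation-quality key as
#'   `info` when present. Variants are kept in file order.
#' @export
read_genotypes_vcf <- function(path, counted_allele = c("alt", "ref")) {
  counted_allele <- match.arg(counted_allele)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(fix$ID[multi], collapse = ", "))
  if (anyDuplicated(fix$ID))
    stop("duplicate variant id(s): ",
         paste(unique(fix$ID[duplicated(fix$ID)]), collapse = ", "))

  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  has_gt <- "GT" %in% fmt_keys
  has_ds <- "DS" %in% fmt_keys
  if (!has_gt && !has_ds)
    stop("VCF carries neither GT nor DS FORMAT fields")

  n_var <- nrow(fix)
  sample_ids <- colnames(v@gt)[-1]
  dos <- matrix(NA_real_, length(sample_ids), n_var)

  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    alt_count <- matrix(NA_real_, n_var, length(sample_ids))
    known <- !is.na(gt) & !grepl("\\.", gt)
    alt_count[known] <- vapply(strsplit(gt[known], "[/|]"),
                               function(a) sum(a == "1"), numeric(1))
    dos <- t(alt_count)
  }
  if (has_ds) {
    ds <- suppressWarnings(
      vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    tds <- t(ds)
    dos[!is.na(tds)] <- tds[!is.na(tds)]
  }

  info <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "INFO")))
  if (counted_allele == "alt") {
    a1 <- fix$ALT; a2 <- fix$REF
  } else {
    a1 <- fix$REF; a2 <- fix$ALT
    dos <- 2 - dos
  }
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         a1 = a1, a2 = a2, info = info,
                         stringsAsFactors = FALSE)
  genotype_matrix(sample_ids, variants, dos)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 with `GT:DS` genotypes. `DS` preserves dosages at
#' full precision so that a write/read round trip through
#' [read_genotypes_vcf()] reproduces them exactly; `GT` is the hard call
#' (rounded dosage) or `./.` for missing. The counted allele is written as ALT.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  v <- g$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           if (!all(is.na(v$info)))
             "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  gt_str <- function(d) {
    out <- rep("./.:.", length(d))
    ok <- !is.na(d)
    hc <- hard_calls(d[ok])
    out[ok] <- paste0(c("0/0", "0/1", "1/1")[hc + 1], ":",
                      vapply(d[ok], format, character(1), digits = 15))
    out
  }
  rows <- vapply(seq_len(nrow(v)), function(j) {
    inf <- if (is.na(v$info[j])) "." else paste0("INFO=", format(v$info[j]))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$a2[j], v$a1[j], ".", "PASS",
            inf, "GT:DS", gt_str(g$dosages[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Column-name synonyms accepted in summary-statistics headers.
.sumstats_synonyms <- list(
  id = c("id", "snp", "rsid", "variant_id", "markername"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "ea", "allele1"),
  other_allele = c("other_allele", "a2", "oa", "allele2", "ref_allele"),
  beta = c("beta", "b", "effect", "log_odds"),
  se = c("se", "stderr", "standard_error"),
  p = c("p", "pval", "p_value", "pvalue"))

#' Read GWAS summary statistics from TSV
#'
#' Expects a tab-separated file whose header provides (under any of the usual
#' synonyms) variant id, effect and other allele, log-odds `beta`, `se` and
#' `p`. Rows with unparseable numerics, `se <= 0`, or `p` outside (0, 1] are
#' dropped with a warning stating the count. Odds-ratio input is not
#' auto-logged: a file with an `OR` column but no beta column is rejected.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `id`, `chrom`, `pos` (NA when absent),
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`.
#' @export
read_summary_stats <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(raw))
  pick <- function(field) {
    hit <- which(nm %in% .sumstats_synonyms[[field]])
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  mandatory <- c("id", "effect_allele", "other_allele", "beta", "se", "p")
  got <- lapply(setNames(mandatory, mandatory), pick)
  missing <- mandatory[vapply(got, is.null, logical(1))]
  if ("beta" %in% missing && "or" %in% nm)
    stop("summary statistics provide 'OR' but no beta column; ",
         "odds ratios are not auto-logged - supply log-odds as 'beta'")
  if (length(missing))
    stop("summary statistics missing mandatory column(s): ",
         paste(missing, collapse = ", "),
         " (expected header: ", paste(mandatory, collapse = ", "), ")")
  out <- data.frame(
    id = as.character(got$id),
    chrom = if (!is.null(pick("chrom"))) as.character(pick("chrom")) else NA_character_,
    pos = if (!is.null(pick("pos")))
      suppressWarnings(as.integer(pick("pos"))) else NA_integer_,
    effect_allele = toupper(as.character(got$effect_allele)),
    other_allele = toupper(as.character(got$other_allele)),
    beta = suppressWarnings(as.numeric(got$beta)),
    se = suppressWarnings(as.numeric(got$se)),
    p = suppressWarnings(as.numeric(got$p)),
    stringsAsFactors = FALSE)
  ok <- is.finite(out$beta) & is.finite(out$se) & out$se > 0 &
    is.finite(out$p) & out$p > 0 & out$p <= 1
  if (any(!ok)) {
    warning(sum(!ok), " summary-statistic row(s) dropped ",
            "(unparseable numerics, se <= 0, or p outside (0, 1])")
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read trios from a FAM-dialect pedigree file
#'
#' Six whitespace-separated columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, 0 = unknown), phenotype
#' (1 = control, 2 = case, -9/0 = missing). Rows with both parental ids
#' non-zero define trios.
#'
#' @param path path to the pedigree file.
#' @return list with `pedigree` (the full table) and `trios` (data.frame
#'   `father_id`, `mother_id`, `child_id`).
#' @export
read_trios_fam <- function(path) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("family_id", "id", "father_id", "mother_id",
                                  "sex", "phenotype"))
  ped$id <- as.character(ped$id)
  ped$father_id <- as.character(ped$father_id)
  ped$mother_id <- as.character(ped$mother_id)
  is_child <- ped$father_id != "0" & ped$mother_id != "0"
  trios <- data.frame(father_id = ped$father_id[is_child],
                      mother_id = ped$mother_id[is_child],
                      child_id = ped$id[is_child],
                      stringsAsFactors = FALSE)
  validate_trios(trios)
  list(pedigree = ped, trios = trios)
}

#' Write a pedigree FAM file
#'
#' @param pedigree data.frame with columns `family_id`, `id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trios_fam <- function(pedigree, path) {
  write.table(pedigree[, c("family_id", "id", "father_id", "mother_id",
                           "sex", "phenotype")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

validate_trios <- function(trios) {
  ids <- c(trios$father_id, trios$mother_id, trios$child_id)
  same <- trios$father_id == trios$mother_id |
    trios$father_id == trios$child_id | trios$mother_id == trios$child_id
  if (any(same))
    stop("trio member ids must be distinct (child ",
         paste(trios$child_id[same], collapse = ", "), ")")
  if (anyDuplicated(trios$child_id))
    stop("child appears in more than one trio: ",
         paste(unique(trios$child_id[duplicated(trios$child_id)]),
               collapse = ", "))
  invisible(trios)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; numeric columns formatted at 6
#' significant digits; rows written in input order.
#'
#' @param records a data.frame (possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(records, path) {
  out <- as.data.frame(records)
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
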