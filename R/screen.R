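#' Classify SNVs/indels under the qualifying rare-variant rules
#'
#' A variant qualifies when it lies in a known dominant-acting epilepsy/ID
#' gene AND is loss-of-function, or missense with MPC > 2, AND is absent
#' from population databases AND was seen at most 3 times in the dataset.
#' Missense variants without an MPC score never qualify.
#'
#' @param v data.frame with columns `gene_in_dominant_panel` (logical),
#'   `consequence` (`"lof"`, `"missense"`, `"synonymous"`, `"other"`),
#'   `mpc` (numeric or NA), `in_population_db` (logical), `dataset_count`
#'   (integer >= 1).
#' @return logical vector; attribute `audit` is a data.frame of per-rule
#'   pass/fail flags (`panel`, `consequence`, `absent_db`, `rare_in_dataset`).
#' @export
classify_snv <- function(v) {
  mpc <- ifelse(is.na(v$mpc), -Inf, v$mpc)
  panel <- v$gene_in_dominant_panel
  csq <- v$consequence == "lof" | (v$consequence == "missense" & mpc > 2)
  absent_db <- !v$in_population_db
  rare <- v$dataset_count <= 3
  out <- panel & csq & absent_db & rare
  attr(out, "audit") <- data.frame(panel = panel, consequence = csq,
                                   absent_db = absent_db,
                                   rare_in_dataset = rare)
  out
}

#' Classify CNVs under the qualifying rules
#'
#' A CNV qualifies when it is longer than 2 Mb (strict), or overlaps a known
#' epilepsy gene or hotspot, or overlaps a gene with pLI > 0.9 — an OR over
#' the three clauses, exactly as the screen defines them.
#'
#' @param cnv data.frame with columns `length_bp`,
#'   `overlaps_epilepsy_gene_or_hotspot`, `overlaps_pli_gt_0_9_gene`.
#' @return logical vector; attribute `audit` holds the per-clause flags
#'   (`length`, `hotspot`, `pli`).
#' @export
classify_cnv <- function(cnv) {
  len <- cnv$length_bp > 2e6
  hot <- cnv$overlaps_epilepsy_gene_or_hotspot
  pli <- cnv$overlaps_pli_gt_0_9_gene
  out <- len | hot | pli
  attr(out, "audit") <- data.frame(length = len, hotspot = hot, pli = pli)
  out
}

#' Assign screen status to cases from annotated variant tables
#'
#' A case is screen-positive when it carries at least one qualifying SNV or
#' CNV, screen-negative when it appears in the variant tables but has no
#' qualifying record, and unknown when it is absent from both tables (no
#' rare-variant data).
#'
#' @param case_ids character vector of case sample ids.
#' @param snvs SNV annotation table (see [classify_snv()]; needs `case_id`),
#'   or NULL.
#' @param cnvs CNV annotation table (see [classify_cnv()]; needs `case_id`),
#'   or NULL.
#' @return data.frame of class `screen_assignment`: `case_id`, `status`,
#'   `n_qualifying`, `qualifying_records` (comma-separated record ids);
#'   attributes `snv_audit` / `cnv_audit` carry the per-rule flags.
#' @export
assign_screen_status <- function(case_ids, snvs = NULL, cnvs = NULL) {
  case_ids <- as.character(case_ids)
  check_refs <- function(tab, what) {
    if (!is.null(tab) && nrow(tab) > 0) {
      bad <- setdiff(unique(tab$case_id), case_ids)
      if (length(bad))
        stop(what, " table references unknown case id(s): ",
             paste(bad, collapse = ", "))
    }
  }
  check_refs(snvs, "SNV"); check_refs(cnvs, "CNV")

  has_data <- character(0)
  qual_by_case <- setNames(vector("list", length(case_ids)), case_ids)
  snv_audit <- cnv_audit <- NULL
  if (!is.null(snvs) && nrow(snvs) > 0) {
    q <- classify_snv(snvs)
    snv_audit <- cbind(snvs[, c("case_id", "variant_id")], attr(q, "audit"),
                       qualifying = as.logical(q))
    has_data <- union(has_data, snvs$case_id)
    for (i in which(q))
      qual_by_case[[snvs$case_id[i]]] <-
        c(qual_by_case[[snvs$case_id[i]]], snvs$variant_id[i])
  }
  if (!is.null(cnvs) && nrow(cnvs) > 0) {
    q <- classify_cnv(cnvs)
    cnv_audit <- cbind(cnvs[, c("case_id", "cnv_id")], attr(q, "audit"),
                       qualifying = as.logical(q))
    has_data <- union(has_data, cnvs$case_id)
    for (i in which(q))
      qual_by_case[[cnvs$case_id[i]]] <-
        c(qual_by_case[[cnvs$case_id[i]]], cnvs$cnv_id[i])
  }
  n_qual <- vapply(qual_by_case, length, integer(1))
  status <- ifelse(n_qual > 0, "positive",
                   ifelse(case_ids %in% has_data, "negative", "unknown"))
  out <- data.frame(case_id = case_ids, status = status,
                    n_qualifying = unname(n_qual),
                    qualifying_records = vapply(qual_by_case, paste,
                                                character(1),
                                                collapse = ","),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "snv_audit") <- snv_audit
  attr(out, "cnv_audit") <- cnv_audit
  class(out) <- c("screen_assignment", "data.frame")
  out
}
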