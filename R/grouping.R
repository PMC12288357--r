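# CpG stratification into evidence groups and classification of each
# association into one of four genetic-influence outcomes.

#' Default thresholds for CpG group assignment
#'
#' @param rph_g1 |Rph| threshold for group G1 (default 0.2).
#' @param rph_min |Rph| threshold common to G2-G4 (default 0.1).
#' @param ra_high |Ra| threshold for G2 (default 0.5).
#' @param ra_low |Ra| ceiling for G3 (default 0.1).
#' @param alpha Significance level for the one-sided path tests.
#' @return Named list of thresholds.
#' @export
group_thresholds <- function(rph_g1 = 0.2, rph_min = 0.1, ra_high = 0.5,
                             ra_low = 0.1, alpha = 0.05) {
  stopifnot(rph_g1 > 0, rph_min > 0, ra_high > 0, ra_low > 0,
            alpha > 0, alpha < 1)
  list(rph_g1 = rph_g1, rph_min = rph_min, ra_high = ra_high,
       ra_low = ra_low, alpha = alpha)
}

#' CpG-to-SNP shared-evidence map
#'
#' Exact string-match intersection: for each CpG in the meQTL map, the set of
#' its meQTL SNPs that also appear in the trait's GWAS SNP list. CpGs with an
#' empty intersection are omitted; duplicate meQTL rows are deduplicated.
#'
#' @param meqtl data.frame with columns `snp` and `cpg`.
#' @param gwas Character vector of GWAS SNP identifiers.
#' @return Named list: CpG id -> character vector of shared SNPs.
#' @export
shared_snps <- function(meqtl, gwas) {
  if (is.null(meqtl) || nrow(meqtl) == 0L || length(gwas) == 0L)
    return(stats::setNames(list(), character(0)))
  hit <- meqtl[meqtl$snp %in% gwas, , drop = FALSE]
  if (nrow(hit) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(hit$snp, hit$cpg), function(s) sort(unique(s)))
}

#' Assign CpGs to evidence groups G1-G4
#'
#' Applies the four membership rules to a twin-SEM scan table, on absolute
#' correlation values (memberships may overlap, except G2/G3 which are
#' disjoint by construction):
#' \itemize{
#'   \item G1: significant Rph with |Rph| >= `rph_g1`.
#'   \item G2: significant Rph, |Rph| > `rph_min`, significant Ra with
#'     |Ra| > `ra_high`.
#'   \item G3: significant Rph, |Rph| > `rph_min`, non-significant Ra with
#'     |Ra| < `ra_low` (conjunction).
#'   \item G4: significant Rph, |Rph| > `rph_min`, and at least one meQTL SNP
#'     shared with the trait's GWAS list.
#' }
#' Significance of Rph is the joint cross-path test (`p_rph`), of Ra the
#' genetic cross-path test (`p_ra`), both at level `alpha`.
#'
#' @param sem data.frame from [twinsem_scan()] (one row per CpG x trait).
#' @param shared Named list from [shared_snps()] (CpG -> SNPs), or `NULL`.
#' @param thresholds A [group_thresholds()] list.
#' @return data.frame `cpg, trait, rph, p_rph, ra, p_ra, g1, g2, g3, g4,
#'   shared_snps` (comma-separated); unknown CpG ids referenced by `shared`
#'   are reported via a warning and the `"unknown_ids"` attribute.
#' @export
assign_groups <- function(sem, shared = NULL,
                          thresholds = group_thresholds()) {
  if (anyDuplicated(paste(sem$cpg, sem$trait)))
    stop("sem table must have unique cpg x trait rows")
  th <- thresholds
  snps <- if (is.null(shared)) character(nrow(sem))
  else vapply(sem$cpg, function(id) {
    s <- shared[[id]]
    if (is.null(s)) "" else paste(s, collapse = ",")
  }, "")
  unknown <- if (is.null(shared)) character(0)
  else setdiff(names(shared), sem$cpg)
  if (length(unknown))
    warning(length(unknown), " CpG id(s) in the shared-SNP map are absent ",
            "from the scan table: ", paste(utils::head(unknown, 5),
                                           collapse = ", "))
  sig_rph <- is.finite(sem$p_rph) & sem$p_rph < th$alpha
  sig_ra <- is.finite(sem$p_ra) & sem$p_ra < th$alpha
  base <- sig_rph & abs(sem$rph) > th$rph_min
  out <- data.frame(cpg = sem$cpg, trait = sem$trait,
                    rph = sem$rph, p_rph = sem$p_rph,
                    ra = sem$ra, p_ra = sem$p_ra,
                    g1 = sig_rph & abs(sem$rph) >= th$rph_g1,
                    g2 = base & sig_ra & abs(sem$ra) > th$ra_high,
                    g3 = base & !sig_ra & abs(sem$ra) < th$ra_low,
                    g4 = base & snps != "",
                    shared_snps = snps, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unknown_ids") <- unknown
  out
}

outcome_levels <- function() {
  c("independent", "genetically_driven", "confounded", "null")
}

#' Classify an association into one of four genetic-influence outcomes
#'
#' Deterministic rule table on the two significance flags
#' (FDR-adjusted p < `alpha`):
#' full-population significant and MZ-paired significant -> `independent`
#' (association survives genetic control); significant only in the full
#' population -> `genetically_driven`; significant only within MZ pairs ->
#' `confounded` (genetic effects mask the association); neither -> `null`.
#'
#' @param full,paired data.frames with columns `cpg` and `fdr_p` for the same
#'   CpG set (full-population and MZ-paired designs).
#' @param alpha Significance level (default 0.05).
#' @return data.frame `cpg, sig_full, sig_paired, outcome` (factor with the
#'   four levels), rows matched on `cpg`.
#' @export
classify_outcome <- function(full, paired, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m <- match(full$cpg, paired$cpg)
  if (anyNA(m)) stop("CpG(s) missing from the paired results: ",
                     paste(utils::head(full$cpg[is.na(m)], 5), collapse = ", "))
  sf <- full$fdr_p < alpha
  sp <- paired$fdr_p[m] < alpha
  lab <- ifelse(sf & sp, "independent",
                ifelse(sf & !sp, "genetically_driven",
                       ifelse(!sf & sp, "confounded", "null")))
  data.frame(cpg = full$cpg, sig_full = sf, sig_paired = sp,
             outcome = factor(lab, levels = outcome_levels()),
             stringsAsFactors = FALSE)
}

#' Cross-tabulate group membership and association outcomes
#'
#' @param assignments Output of [assign_groups()].
#' @param outcomes Output of [classify_outcome()] for the same CpGs.
#' @return List with `counts` (data.frame trait x group x outcome, including
#'   an `all` pseudo-group for every scanned CpG), and `overlaps` (pairwise
#'   group intersection counts).
#' @export
summarize_groups <- function(assignments, outcomes) {
  m <- match(assignments$cpg, outcomes$cpg)
  oc <- factor(rep(NA_character_, nrow(assignments)),
               levels = outcome_levels())
  oc[!is.na(m)] <- outcomes$outcome[m[!is.na(m)]]
  groups <- c("all", "g1", "g2", "g3", "g4")
  traits <- unique(assignments$trait)
  if (length(traits) == 0L) traits <- character(0)
  counts <- expand.grid(trait = traits, group = groups,
                        outcome = c(outcome_levels(), "unclassified"),
                        stringsAsFactors = FALSE)
  counts$n <- mapply(function(tr, g, o) {
    in_g <- assignments$trait == tr &
      (if (g == "all") TRUE else assignments[[g]])
    in_o <- if (o == "unclassified") is.na(oc) else !is.na(oc) & oc == o
    sum(in_g & in_o)
  }, counts$trait, counts$group, counts$outcome)
  counts <- counts[counts$n > 0 | counts$outcome != "unclassified", ]
  rownames(counts) <- NULL
  gm <- as.matrix(assignments[, c("g1", "g2", "g3", "g4")])
  overlaps <- crossprod(gm * 1L)
  list(counts = counts, overlaps = overlaps)
}
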