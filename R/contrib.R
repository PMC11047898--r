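as_counts <- function(x) {
  if (inherits(x, "hap_incidence")) x <- x$counts
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop("empty haplotype incidence", call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("incidence counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(x) == 0)) {
    stop("every haplotype must occur in at least one population",
         call. = FALSE)
  }
  x
}

#' Equal-share haplotype richness contribution (R_T)
#'
#' Each distinct haplotype carries one unit of richness, split equally
#' among the populations in which it occurs: a private haplotype
#' contributes 1 to its population, a haplotype shared by `m` populations
#' contributes `1/m` to each. Per population,
#' \deqn{R_T(k) = \sum_{h:\,N_{hk} > 0} 1 / m_h,}
#' so the R_T values always sum to the number of distinct haplotypes in
#' the group. This depends only on presence/absence, not on how many
#' copies of a haplotype were sampled.
#'
#' @param incidence A [collapse_haplotypes()] result, or a haplotypes x
#'   populations count matrix.
#' @return Named numeric vector of per-population R_T.
#' @export
equal_share_richness <- function(incidence) {
  counts <- as_counts(incidence)
  pres <- counts > 0
  m_h <- rowSums(pres)
  colSums(pres / m_h)
}

#' Within-population diversity contribution (R_S)
#'
#' The share of the group's haplotype inventory a population would hold
#' if inventories were compared head-count style: `R_S(k) = H_k / K`,
#' where `H_k` is the number of distinct haplotypes observed in
#' population `k` and `K` the number of populations in the group.
#'
#' @inheritParams equal_share_richness
#' @return Named numeric vector of per-population R_S.
#' @export
within_contribution <- function(incidence) {
  counts <- as_counts(incidence)
  colSums(counts > 0) / ncol(counts)
}

#' Distinctiveness contribution (R_D)
#'
#' The part of the total richness contribution not explained by the size
#' of a population's haplotype inventory: `R_D = R_T - R_S`. It is zero
#' when every haplotype is shared by all populations and grows with the
#' number of private haplotypes; it is never negative.
#'
#' @param R_T,R_S Vectors from [equal_share_richness()] and
#'   [within_contribution()] on the same incidence.
#' @return Named numeric vector of per-population R_D.
#' @export
distinctiveness_contribution <- function(R_T, R_S) {
  if (length(R_T) != length(R_S)) {
    stop("R_T and R_S must align", call. = FALSE)
  }
  R_T - R_S
}

#' Contribution rates (C%)
#'
#' Converts a contribution vector into a zero-sum percentage: each
#' population's deviation from the group mean contribution, scaled by the
#' summed per-population haplotype counts,
#' \deqn{C_X(k)\% = 100\,(R_X(k) - \bar{R}_X) / \sum_j H_j.}
#' Positive rates mark populations whose presence raises the group's
#' diversity, distinctiveness or overall richness above average — the
#' conservation-priority signal.
#'
#' @param R_X Per-population contribution vector (R_S, R_D or R_T).
#' @param H Per-population haplotype counts of the same group (their sum
#'   is the denominator).
#' @return Named numeric vector of percentages summing to zero.
#' @export
contribution_rates <- function(R_X, H) {
  total <- sum(H)
  if (total <= 0) stop("sum of haplotype counts must be > 0", call. = FALSE)
  100 * (R_X - mean(R_X)) / total
}

# One contribution table for one group of >= 1 populations (zero-haplotype
# populations already removed).
contribution_table <- function(counts, group_label) {
  counts <- as_counts(counts)
  H <- colSums(counts > 0)
  R_S <- within_contribution(counts)
  R_T <- equal_share_richness(counts)
  R_D <- distinctiveness_contribution(R_T, R_S)
  single <- ncol(counts) == 1L
  if (single) {
    # A single-population group: rates compare a population with the group
    # mean, which is itself — undefined, reported as NA; the population is
    # still flagged as the (trivial) priority.
    crs <- crd <- crt <- NA_real_
    priority <- TRUE
  } else {
    crs <- contribution_rates(R_S, H)
    crd <- contribution_rates(R_D, H)
    crt <- contribution_rates(R_T, H)
    priority <- crt > 0
  }
  out <- data.frame(
    population = colnames(counts), H = as.integer(H),
    R_S = unname(R_S), R_D = unname(R_D), R_T = unname(R_T),
    C_RS_pct = unname(crs), C_RD_pct = unname(crd), C_RT_pct = unname(crt),
    priority = unname(priority),
    stringsAsFactors = FALSE
  )
  attr(out, "group_label") <- group_label
  attr(out, "n_haplotypes") <- nrow(counts)
  out
}

#' Genetic-contribution decomposition, overall and per clade
#'
#' Computes, for the full haplotype incidence and (optionally) for each
#' evolutionary clade, the per-population contribution decomposition:
#' haplotype count H, within-population diversity contribution R_S,
#' distinctiveness contribution R_D, total richness contribution
#' R_T = R_S + R_D, and the zero-sum contribution rates C_RS%, C_RD%,
#' C_RT%. Within a clade only the populations carrying at least one of
#' the clade's haplotypes enter the calculation (K shrinks accordingly);
#' a clade held by a single population is reported descriptively with
#' undefined rates and that population flagged as the priority.
#'
#' @param incidence A [collapse_haplotypes()] result (or count matrix).
#' @param clades Optional named character vector `haplotype_id -> clade`
#'   covering every haplotype (see [lift_clade_assignment()] for
#'   per-sequence maps).
#' @return Named list of contribution tables: `overall`, then one per
#'   clade (in order of first appearance). Each table has columns
#'   `population`, `H`, `R_S`, `R_D`, `R_T`, `C_RS_pct`, `C_RD_pct`,
#'   `C_RT_pct`, `priority`, with attributes `group_label` and
#'   `n_haplotypes`.
#' @export
contribution_analysis <- function(incidence, clades = NULL) {
  counts <- as_counts(incidence)
  if (ncol(counts) < 2L) {
    stop("contribution analysis needs at least 2 populations", call. = FALSE)
  }
  tables <- list(overall = contribution_table(counts, "overall"))
  if (!is.null(clades)) {
    hap_ids <- rownames(counts)
    if (is.null(hap_ids)) hap_ids <- as.character(seq_len(nrow(counts)))
    missing <- setdiff(hap_ids, names(clades))
    if (length(missing) > 0L) {
      stop("clade assignment missing for haplotype '", missing[1L], "'",
           call. = FALSE)
    }
    lab <- unname(clades[hap_ids])
    for (cl in unique(lab)) {
      sub <- counts[lab == cl, , drop = FALSE]
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      if (ncol(sub) == 0L) {
        stop("clade '", cl, "' has no haplotypes", call. = FALSE)
      }
      tables[[cl]] <- contribution_table(sub, cl)
    }
  }
  tables
}

#' Partition populations by the sign of their total contribution rate
#'
#' @param table A contribution table from [contribution_analysis()].
#' @return List with `group_label`, `positive` and `negative` population
#'   vectors (each in decreasing order of C_RT%), and `undefined` (the
#'   populations of a single-population group, where rates do not apply).
#' @export
classify_priority <- function(table) {
  stopifnot(is.data.frame(table), "C_RT_pct" %in% names(table))
  crt <- table$C_RT_pct
  if (all(is.na(crt))) {
    return(list(group_label = attr(table, "group_label"),
                positive = character(0), negative = character(0),
                undefined = table$population))
  }
  ord <- order(-crt)
  pop <- table$population[ord]
  crt <- crt[ord]
  list(group_label = attr(table, "group_label"),
       positive = pop[crt > 0],
       negative = pop[crt < 0],
       undefined = character(0))
}
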