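#' Select alignment columns used for all statistics
#'
#' Under the `complete_deletion` policy every column containing a gap
#' (`-`) or an ambiguous base (`N`) in any sequence is removed, so that all
#' haplotype and diversity statistics are computed on a single consistent
#' site set.
#'
#' @param aln A [hap_alignment].
#' @param policy Gap/missing-data policy; only `"complete_deletion"` is
#'   implemented.
#' @return Integer vector of retained column indices (1-based).
#' @export
select_used_columns <- function(aln, policy = "complete_deletion") {
  stopifnot(inherits(aln, "hap_alignment"))
  policy <- match.arg(policy, "complete_deletion")
  m <- alignment_matrix(aln)
  keep <- which(colSums(m == "-" | m == "N") == 0L)
  if (length(keep) == 0L) {
    stop("no columns free of gaps/N remain under complete deletion",
         call. = FALSE)
  }
  keep
}

population_order <- function(pops) {
  ord <- attr(pops, "pop_order")
  if (is.null(ord)) ord <- unique(unname(pops))
  ord
}

#' Collapse an alignment into a haplotype-by-population incidence
#'
#' Sequences identical over the used columns are collapsed into one
#' haplotype; haplotypes are labelled `Hap_1`, `Hap_2`, ... in order of
#' first appearance in the alignment. The central result is the count
#' matrix `counts[h, p]` of occurrences of haplotype `h` in population `p`,
#' which both priority models consume.
#'
#' @param aln A [hap_alignment].
#' @param pops Named character vector `sequence_id -> population` covering
#'   the alignment (see [read_population_map()]).
#' @param used Columns to consider; defaults to [select_used_columns()].
#' @return An object of class `hap_incidence`: list with `haplotype_ids`,
#'   `haplotype_seqs` (canonical residue string of each haplotype over the
#'   used columns), `counts` (haplotypes x populations integer matrix),
#'   `used_columns`, `populations` (order of first appearance in the map),
#'   and `sequence_haplotype` (named vector `sequence_id -> haplotype_id`).
#' @examples
#' aln <- hap_alignment(c("a", "b", "c"), c("ACGT", "ACGT", "ACGA"))
#' pops <- c(a = "P1", b = "P1", c = "P2")
#' collapse_haplotypes(aln, pops)$counts
#' @export
collapse_haplotypes <- function(aln, pops, used = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  missing <- setdiff(aln$ids, names(pops))
  if (length(missing) > 0L) {
    stop("no population assigned to sequence '", missing[1L], "'",
         call. = FALSE)
  }
  if (is.null(used)) used <- select_used_columns(aln)
  if (length(used) == 0L) stop("`used` must be non-empty", call. = FALSE)
  m <- alignment_matrix(aln)[, used, drop = FALSE]
  keys <- apply(m, 1L, paste, collapse = "")
  uniq <- unique(keys)
  hap_ids <- paste0("Hap_", seq_along(uniq))
  hap_of_seq <- stats::setNames(hap_ids[match(keys, uniq)], aln$ids)
  pop_levels <- population_order(pops)
  counts <- table(
    factor(hap_of_seq, levels = hap_ids),
    factor(unname(pops[aln$ids]), levels = pop_levels)
  )
  counts <- matrix(as.integer(counts), nrow = length(hap_ids),
                   dimnames = list(hap_ids, pop_levels))
  structure(
    list(haplotype_ids = hap_ids,
         haplotype_seqs = stats::setNames(uniq, hap_ids),
         counts = counts,
         used_columns = used,
         populations = pop_levels,
         sequence_haplotype = hap_of_seq),
    class = "hap_incidence"
  )
}

#' @export
print.hap_incidence <- function(x, ...) {
  cat("<hap_incidence> ", nrow(x$counts), " haplotypes x ",
      ncol(x$counts), " populations (", sum(x$counts), " sequences, ",
      length(x$used_columns), " sites)\n", sep = "")
  invisible(x)
}

#' Classify variable sites
#'
#' Over a set of aligned sequences, a used column is *polymorphic* (Nps)
#' if at least two distinct residues occur; among polymorphic columns, a
#' column is *parsimony informative* (Pis) if at least two residues each
#' occur in at least two sequences, and a *singleton variable site* (Svs)
#' otherwise (at most one residue reaches two copies, i.e. every minority
#' residue is carried by a single sequence). Polymorphic sites therefore
#' partition exactly into singleton plus informative sites.
#'
#' @param aln A [hap_alignment] (or subset of interest).
#' @param used Columns to consider (default: all gap/N-free columns).
#' @param ids Optional subset of sequence ids to restrict to.
#' @return List with integer column vectors `polymorphic_sites`,
#'   `singleton_sites`, `parsimony_informative_sites`, counts `Nps`, `Svs`,
#'   `Pis`, and a `degenerate` flag (fewer than 2 sequences).
#' @export
classify_sites <- function(aln, used = NULL, ids = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(used)) used <- select_used_columns(aln)
  m <- alignment_matrix(aln)
  if (!is.null(ids)) {
    if (!all(ids %in% aln$ids)) stop("unknown sequence id", call. = FALSE)
    m <- m[ids, , drop = FALSE]
  }
  if (nrow(m) < 2L) {
    return(list(polymorphic_sites = integer(0), singleton_sites = integer(0),
                parsimony_informative_sites = integer(0),
                Nps = 0L, Svs = 0L, Pis = 0L, degenerate = TRUE))
  }
  m <- m[, used, drop = FALSE]
  poly <- logical(length(used))
  info <- logical(length(used))
  for (j in seq_along(used)) {
    tab <- tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), 4L)
    poly[j] <- sum(tab > 0L) >= 2L
    info[j] <- sum(tab >= 2L) >= 2L
  }
  list(
    polymorphic_sites = used[poly],
    singleton_sites = used[poly & !info],
    parsimony_informative_sites = used[info],
    Nps = sum(poly), Svs = sum(poly & !info), Pis = sum(info),
    degenerate = FALSE
  )
}

#' Haplotype diversity (Hd)
#'
#' Nei's unbiased gene (haplotype) diversity for one population:
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` with haplotype frequencies
#' `p_i = count_i / n`. Equivalently, the probability that two sequences
#' drawn without replacement carry different haplotypes. The standard
#' error follows Nei (1987, eq. 8.12).
#'
#' @param counts Non-negative integer vector of per-haplotype counts for
#'   one population.
#' @return List with `Hd`, `se`, `n` and a `degenerate` flag (`n < 2`, for
#'   which Hd is reported as 0).
#' @examples
#' haplotype_diversity(c(2, 2))$Hd  # 2/3
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) {
    return(list(Hd = 0, se = NA_real_, n = n, degenerate = TRUE))
  }
  p <- counts / n
  s2 <- sum(p^2)
  hd <- n / (n - 1) * (1 - s2)
  # Nei (1987) variance of gene diversity
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(Hd = hd, se = sqrt(max(v, 0)), n = n, degenerate = FALSE)
}

# Pairwise difference-count matrix over the used columns (n x n, symmetric).
pairwise_differences <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(ncol(m))) {
    d <- d + outer(m[, j], m[, j], "!=")
  }
  d
}

#' Nucleotide diversity (Pi) and mean pairwise differences (K)
#'
#' For one population, `K` is the mean number of differing used columns
#' over all unordered sequence pairs and `Pi = K / L` with `L` the number
#' of used columns.
#'
#' @param aln A [hap_alignment].
#' @param ids Sequence ids of the population (default: all).
#' @param used Columns to consider (default: all gap/N-free columns).
#' @return List with `K`, `Pi`, `L_used`, `n` and a `degenerate` flag.
#' @export
nucleotide_stats <- function(aln, ids = NULL, used = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(used)) used <- select_used_columns(aln)
  if (is.null(ids)) ids <- aln$ids
  n <- length(ids)
  if (n < 2L) {
    return(list(K = 0, Pi = 0, L_used = length(used), n = n,
                degenerate = TRUE))
  }
  m <- alignment_matrix(aln)[ids, used, drop = FALSE]
  d <- pairwise_differences(m)
  K <- sum(d[upper.tri(d)]) / choose(n, 2)
  list(K = K, Pi = K / length(used), L_used = length(used), n = n,
       degenerate = FALSE)
}

#' Per-population diversity panel
#'
#' Computes, for every population, the sample size S, number of haplotypes
#' H, site classification (Nps, Pis, Svs) over that population's
#' sequences, haplotype diversity Hd (with standard error), nucleotide
#' diversity Pi, and mean pairwise differences K — the panel that feeds
#' the composite diversity score.
#'
#' @param aln A [hap_alignment].
#' @param pops Named character vector `sequence_id -> population`.
#' @param used Columns to consider (default: all gap/N-free columns).
#' @return Data frame with one row per population, columns `population`,
#'   `S`, `H`, `Nps`, `Pis`, `Svs`, `Hd`, `Hd_se`, `Pi`, `K`, `degenerate`.
#'   Populations of a single sequence carry zeros and `degenerate = TRUE`.
#' @export
diversity_panel <- function(aln, pops, used = NULL) {
  if (is.null(used)) used <- select_used_columns(aln)
  inc <- collapse_haplotypes(aln, pops, used)
  out <- lapply(inc$populations, function(p) {
    ids <- aln$ids[unname(pops[aln$ids]) == p]
    cnt <- inc$counts[, p]
    sc <- classify_sites(aln, used = used, ids = ids)
    hd <- haplotype_diversity(cnt)
    ns <- nucleotide_stats(aln, ids = ids, used = used)
    data.frame(population = p, S = length(ids), H = sum(cnt > 0L),
               Nps = sc$Nps, Pis = sc$Pis, Svs = sc$Svs,
               Hd = hd$Hd, Hd_se = hd$se, Pi = ns$Pi, K = ns$K,
               degenerate = hd$degenerate || ns$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise population p-distance matrix
#'
#' Off-diagonal entries are the mean per-site proportion of differing used
#' columns over all between-population sequence pairs (Dxy, uncorrected);
#' diagonal entries are the corresponding within-population means.
#'
#' @inheritParams diversity_panel
#' @return A `hap_pairwise` object: list with `populations`, `kind =
#'   "distance"`, `values` (symmetric matrix) and `degenerate` (logical
#'   vector flagging single-sequence populations, whose diagonal is `NA`).
#' @export
population_distance_matrix <- function(aln, pops, used = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(used)) used <- select_used_columns(aln)
  lev <- population_order(pops)
  if (length(lev) < 2L) stop("need at least 2 populations", call. = FALSE)
  m <- alignment_matrix(aln)[, used, drop = FALSE]
  d <- pairwise_differences(m) / length(used)
  grp <- unname(pops[aln$ids])
  K <- length(lev)
  vals <- matrix(NA_real_, K, K, dimnames = list(lev, lev))
  degen <- logical(K)
  names(degen) <- lev
  for (a in seq_len(K)) {
    ia <- which(grp == lev[a])
    if (length(ia) < 2L) {
      degen[a] <- TRUE
      vals[a, a] <- NA_real_
    } else {
      da <- d[ia, ia]
      vals[a, a] <- sum(da[upper.tri(da)]) / choose(length(ia), 2)
    }
    if (a < K) for (b in seq((a + 1L), K)) {
      ib <- which(grp == lev[b])
      vals[a, b] <- vals[b, a] <- mean(d[ia, ib, drop = FALSE])
    }
  }
  structure(list(populations = lev, kind = "distance", values = vals,
                 degenerate = degen),
            class = "hap_pairwise")
}

#' Pairwise Fst and gene flow (Nm) matrices
#'
#' Hudson-type pairwise differentiation: `Fst = 1 - Hw / Hb`, where `Hw`
#' is the mean of the two within-population mean pairwise difference
#' counts and `Hb` the mean between-population pairwise difference count.
#' Gene flow uses the island-model transform `Nm = (1 - Fst) / (4 Fst)`,
#' reported as `Inf` (and flagged) when `Fst <= 0`. Small negative Fst
#' estimates are kept as computed and flagged, never silently clamped.
#'
#' @inheritParams diversity_panel
#' @return List of two `hap_pairwise` objects, `fst` and `nm`, each with a
#'   logical `flags` matrix marking undefined or boundary cases.
#' @export
fst_nm_matrix <- function(aln, pops, used = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(used)) used <- select_used_columns(aln)
  lev <- population_order(pops)
  if (length(lev) < 2L) stop("need at least 2 populations", call. = FALSE)
  m <- alignment_matrix(aln)[, used, drop = FALSE]
  d <- pairwise_differences(m)
  grp <- unname(pops[aln$ids])
  K <- length(lev)
  fst <- matrix(NA_real_, K, K, dimnames = list(lev, lev))
  nm <- fst
  flags <- matrix(FALSE, K, K, dimnames = list(lev, lev))
  within_mean <- function(ia) {
    da <- d[ia, ia]
    sum(da[upper.tri(da)]) / choose(length(ia), 2)
  }
  for (a in seq_len(K - 1L)) for (b in seq((a + 1L), K)) {
    ia <- which(grp == lev[a])
    ib <- which(grp == lev[b])
    if (length(ia) < 2L || length(ib) < 2L) {
      flags[a, b] <- flags[b, a] <- TRUE
      next
    }
    hw <- (within_mean(ia) + within_mean(ib)) / 2
    hb <- mean(d[ia, ib, drop = FALSE])
    if (hb == 0) {
      flags[a, b] <- flags[b, a] <- TRUE  # Fst undefined: no divergence
      next
    }
    f <- 1 - hw / hb
    fst[a, b] <- fst[b, a] <- f
    if (f <= 0) {
      flags[a, b] <- flags[b, a] <- TRUE
      nm[a, b] <- nm[b, a] <- Inf
    } else {
      nm[a, b] <- nm[b, a] <- (1 - f) / (4 * f)
    }
  }
  list(
    fst = structure(list(populations = lev, kind = "fst", values = fst,
                         flags = flags), class = "hap_pairwise"),
    nm = structure(list(populations = lev, kind = "nm", values = nm,
                        flags = flags), class = "hap_pairwise")
  )
}

#' @export
print.hap_pairwise <- function(x, digits = 4, ...) {
  cat("<hap_pairwise> kind =", x$kind, "\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Regional haplotype sharing summary
#'
#' Aggregates a haplotype incidence to regions and counts, per region, the
#' haplotypes found in that region only (unique) and, per region pair, the
#' haplotypes present in both.
#'
#' @param incidence A [collapse_haplotypes()] result.
#' @param regions Named character vector `population -> region` covering
#'   all populations of the incidence.
#' @return List with `unique_counts` (named integer vector per region) and
#'   `shared_counts` (symmetric region x region matrix; the diagonal holds
#'   each region's total haplotype count).
#' @export
sharing_summary <- function(incidence, regions) {
  stopifnot(inherits(incidence, "hap_incidence"))
  missing <- setdiff(incidence$populations, names(regions))
  if (length(missing) > 0L) {
    stop("no region for population '", missing[1L], "'", call. = FALSE)
  }
  reg <- unname(regions[incidence$populations])
  lev <- unique(reg)
  pres <- incidence$counts > 0L
  # haplotype x region presence
  rpres <- vapply(lev, function(r) {
    rowSums(pres[, reg == r, drop = FALSE]) > 0L
  }, logical(nrow(pres)))
  rpres <- matrix(rpres, nrow = nrow(pres), dimnames = list(NULL, lev))
  nreg <- rowSums(rpres)
  uniq <- vapply(lev, function(r) sum(rpres[, r] & nreg == 1L), integer(1L))
  shared <- crossprod(rpres)
  list(unique_counts = uniq, shared_counts = shared)
}
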