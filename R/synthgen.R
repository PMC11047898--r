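# Run expr with a private RNG stream seeded by `seed`; the caller's RNG
# state is left untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specify a synthetic multi-population haplotype sample
#'
#' A configuration fixes the haplotype incidence exactly: which
#' populations carry each haplotype and with how many sampled copies.
#' [generate_alignment()] realizes it as a FASTA-ready alignment whose
#' collapse recovers the incidence.
#'
#' @param populations Ordered character vector of population names.
#' @param haplotype_specs Named list; each element is a named integer
#'   vector `population -> copy count` (all counts >= 1) giving the
#'   carriers of one haplotype. Element names become haplotype labels.
#' @param sequence_length Alignment length in bp (default 656, a typical
#'   mtDNA control-region fragment).
#' @param min_pairwise_differences Minimum number of sites at which any
#'   two haplotypes differ (>= 1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `hap_synth_config`.
#' @export
synthetic_config <- function(populations, haplotype_specs,
                             sequence_length = 656L,
                             min_pairwise_differences = 1L,
                             seed = 1L) {
  populations <- as.character(populations)
  if (length(populations) < 1L || anyDuplicated(populations)) {
    stop("populations must be a non-empty set of distinct names",
         call. = FALSE)
  }
  if (length(haplotype_specs) < 1L) {
    stop("need at least one haplotype spec", call. = FALSE)
  }
  if (is.null(names(haplotype_specs)) || any(!nzchar(names(haplotype_specs)))) {
    names(haplotype_specs) <- paste0("hap", seq_along(haplotype_specs))
  }
  for (h in names(haplotype_specs)) {
    spec <- haplotype_specs[[h]]
    if (length(spec) < 1L || is.null(names(spec)) ||
        !all(names(spec) %in% populations) || any(spec < 1)) {
      stop("haplotype spec '", h, "' must give counts >= 1 for known ",
           "populations", call. = FALSE)
    }
  }
  covered <- unique(unlist(lapply(haplotype_specs, names)))
  if (!setequal(covered, populations)) {
    stop("every population must carry at least one haplotype",
         call. = FALSE)
  }
  d <- as.integer(min_pairwise_differences)
  if (d < 1L) stop("min_pairwise_differences must be >= 1", call. = FALSE)
  # disjoint mutation blocks of d sites per haplotype guarantee pairwise
  # distinctness (two haplotypes differ at both their blocks, >= 2d >= d)
  if (length(haplotype_specs) * d > sequence_length) {
    stop("cannot realize ", length(haplotype_specs),
         " distinct haplotypes with blocks of ", d, " sites in ",
         sequence_length, " bp", call. = FALSE)
  }
  structure(
    list(populations = populations, haplotype_specs = haplotype_specs,
         sequence_length = as.integer(sequence_length),
         min_pairwise_differences = d, seed = as.integer(seed)),
    class = "hap_synth_config"
  )
}

#' Generate a synthetic alignment with known haplotype incidence
#'
#' Draws a random ancestral sequence, derives each configured haplotype by
#' substituting a distinct block of `min_pairwise_differences` sites (so
#' all haplotypes are pairwise distinct by construction, no rejection
#' sampling), then replicates each haplotype according to its
#' per-population copy counts. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `alignment` (a [hap_alignment]), `pops` (named vector
#'   `sequence_id -> population` with `pop_order` attribute) and
#'   `expected_counts` (the ground-truth haplotypes x populations matrix,
#'   rows in order of first appearance in the alignment).
#' @export
generate_alignment <- function(config) {
  stopifnot(inherits(config, "hap_synth_config"))
  bases <- c("A", "C", "G", "T")
  L <- config$sequence_length
  d <- config$min_pairwise_differences
  specs <- config$haplotype_specs
  nh <- length(specs)
  hseqs <- with_seed(config$seed, {
    anc <- sample(bases, L, replace = TRUE)
    lapply(seq_len(nh), function(i) {
      s <- anc
      block <- seq((i - 1L) * d + 1L, i * d)
      for (j in block) {
        s[j] <- sample(setdiff(bases, s[j]), 1L)
      }
      paste(s, collapse = "")
    })
  })
  ids <- character(0)
  seqs <- character(0)
  pop_of <- character(0)
  k <- 0L
  for (i in seq_len(nh)) {
    spec <- specs[[i]]
    for (p in names(spec)) {
      for (r in seq_len(spec[[p]])) {
        k <- k + 1L
        ids <- c(ids, sprintf("seq%04d_%s", k, p))
        seqs <- c(seqs, hseqs[[i]])
        pop_of <- c(pop_of, p)
      }
    }
  }
  aln <- hap_alignment(ids, seqs)
  pops <- stats::setNames(pop_of, ids)
  attr(pops, "pop_order") <- config$populations
  expected <- matrix(0L, nrow = nh, ncol = length(config$populations),
                     dimnames = list(names(specs), config$populations))
  for (i in seq_len(nh)) {
    expected[i, names(specs[[i]])] <- as.integer(specs[[i]])
  }
  list(alignment = aln, pops = pops, expected_counts = expected)
}

# Build specs from a private/shared description: `private` is a named
# integer vector population -> number of private haplotypes; `shared` a
# list of character vectors, each the carrier set of one shared haplotype.
specs_from_sharing <- function(populations, private, shared,
                               copies = 1L) {
  specs <- list()
  for (s in shared) {
    specs[[length(specs) + 1L]] <-
      stats::setNames(rep(copies, length(s)), s)
  }
  for (p in names(private)) {
    n <- private[[p]]
    if (n > 0L) for (i in seq_len(n)) {
      specs[[length(specs) + 1L]] <- stats::setNames(copies, p)
    }
  }
  names(specs) <- paste0("hap", seq_along(specs))
  specs
}

#' Seven-population clade-A style fixture
#'
#' A reference configuration emulating an evolutionary clade sampled in
#' seven populations with haplotype inventories (GN 15, GW 12, GD 8,
#' GC 5, GS 2, GE 8, GPO 1), of which exactly three haplotypes are each
#' shared by two populations (GN–GC, GW–GS, GC–GS) and all others are
#' private; 48 distinct haplotypes in total.
#'
#' @param copies Sampled copies per haplotype per carrier population
#'   (default 1; the contribution model is invariant to this).
#' @param seed Seed passed to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
fixture_clade_A <- function(copies = 1L, seed = 101L) {
  pops <- c("GN", "GW", "GD", "GC", "GS", "GE", "GPO")
  specs <- specs_from_sharing(
    pops,
    private = c(GN = 14L, GW = 11L, GD = 8L, GC = 3L, GS = 0L,
                GE = 8L, GPO = 1L),
    shared = list(c("GN", "GC"), c("GW", "GS"), c("GC", "GS")),
    copies = copies
  )
  synthetic_config(pops, specs, seed = seed)
}

#' Four-population clade-C style fixture
#'
#' A reference configuration emulating a clade sampled in four
#' populations with haplotype inventories (GC 3, GE 19, GPO 22, GPR 76),
#' exactly one haplotype shared between GC and GE, all others private;
#' 119 distinct haplotypes in total.
#'
#' @inheritParams fixture_clade_A
#' @return A [synthetic_config()].
#' @export
fixture_clade_C <- function(copies = 1L, seed = 102L) {
  pops <- c("GC", "GE", "GPO", "GPR")
  specs <- specs_from_sharing(
    pops,
    private = c(GC = 2L, GE = 18L, GPO = 22L, GPR = 76L),
    shared = list(c("GC", "GE")),
    copies = copies
  )
  synthetic_config(pops, specs, seed = seed)
}

#' Random haplotype-incidence configuration
#'
#' Property-test driver: each haplotype's carrier set is drawn uniformly
#' from the non-empty subsets of the populations, and each carrier's copy
#' count is 1 + a geometric draw (capped at `max_copies`). Populations
#' left uncovered receive one private haplotype each so the configuration
#' is always valid.
#'
#' @param seed Integer seed.
#' @param n_populations Number of populations, between 2 and 6.
#' @param max_haplotypes Upper bound on random haplotypes (<= 40).
#' @param max_copies Cap on per-population copy counts.
#' @param sequence_length Alignment length for the realized sample.
#' @return A [synthetic_config()].
#' @export
random_incidence <- function(seed, n_populations = 4L, max_haplotypes = 20L,
                             max_copies = 5L, sequence_length = 120L) {
  if (n_populations < 2L || n_populations > 6L) {
    stop("n_populations must be between 2 and 6", call. = FALSE)
  }
  if (max_haplotypes < 1L || max_haplotypes > 40L) {
    stop("max_haplotypes must be between 1 and 40", call. = FALSE)
  }
  pops <- paste0("P", seq_len(n_populations))
  specs <- with_seed(seed, {
    nh <- sample.int(max_haplotypes, 1L)
    sp <- lapply(seq_len(nh), function(i) {
      # carrier set uniform over the 2^K - 1 non-empty subsets
      code <- sample.int(2L^n_populations - 1L, 1L)
      carriers <- pops[bitwAnd(code, 2L^(seq_len(n_populations) - 1L)) > 0L]
      stats::setNames(pmin(1L + stats::rgeom(length(carriers), 0.5),
                           max_copies), carriers)
    })
    for (p in setdiff(pops, unique(unlist(lapply(sp, names))))) {
      sp[[length(sp) + 1L]] <- stats::setNames(1L, p)
    }
    sp
  })
  names(specs) <- paste0("hap", seq_along(specs))
  synthetic_config(pops, specs, sequence_length = sequence_length,
                   seed = seed)
}
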