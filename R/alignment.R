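#' Construct a validated haplotype alignment
#'
#' An alignment is an ordered set of equal-length DNA sequences with unique
#' identifiers, restricted to the alphabet `A`, `C`, `G`, `T`, `N`, `-`.
#' Lowercase residues are uppercased and `U` is mapped to `T` on
#' construction, so all downstream code can assume the canonical alphabet.
#'
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @param seqs Character vector of residue strings, one per id, all the same
#'   length.
#' @return An object of class `hap_alignment`: a list with elements `ids`,
#'   `seqs` (canonicalized residue strings) and `length` (number of
#'   alignment columns).
#' @examples
#' aln <- hap_alignment(c("s1", "s2"), c("ACGT", "ACGA"))
#' aln$length
#' @export
hap_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  }
  if (length(ids) == 0L) {
    stop("alignment must contain at least one sequence", call. = FALSE)
  }
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop("sequence ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id: '", dup, "'", call. = FALSE)
  }
  seqs <- chartr("U", "T", toupper(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "),
         "): input is not an alignment", call. = FALSE)
  }
  if (lens[1L] < 1L) {
    stop("alignment length must be >= 1", call. = FALSE)
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1L], regexpr("[^ACGTN-]", seqs[bad][1L]))
    stop("illegal residue '", ch, "' in sequence '", ids[bad][1L],
         "' (allowed: A C G T N -)", call. = FALSE)
  }
  structure(
    list(ids = ids, seqs = seqs, length = lens[1L]),
    class = "hap_alignment"
  )
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> ", length(x$ids), " sequences x ", x$length,
      " columns\n", sep = "")
  invisible(x)
}

# Character matrix view (sequences x columns); used by all column-wise code.
alignment_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$ids), ncol = aln$length, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Read a FASTA alignment
#'
#' Reads a (wrapped or unwrapped) FASTA file and validates it as an
#' alignment: equal lengths, unique ids, canonical alphabet. The id is the
#' header up to the first whitespace; any description is discarded.
#'
#' @param path Path to a FASTA file.
#' @return A [hap_alignment] object.
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE, forceDNAtolower = FALSE)
  if (length(recs) == 0L) {
    stop("no sequences found in ", path, call. = FALSE)
  }
  hap_alignment(names(recs), unlist(recs, use.names = FALSE))
}

#' Write an alignment to FASTA
#'
#' @param aln A [hap_alignment].
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  stopifnot(inherits(aln, "hap_alignment"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(paste0(">", aln$ids[i]), con)
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Header names recognised when autodetecting a header row in 2-column maps.
.map_header_names <- c("population", "pop", "population_name", "clade",
                       "clade_label", "region", "group")

read_two_column_tsv <- function(path, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", strip.white = TRUE)
  if (ncol(raw) < 2L) {
    stop(what, " must have two tab-separated columns", call. = FALSE)
  }
  raw <- raw[, 1:2]
  if (nrow(raw) > 0L && tolower(raw[1L, 2L]) %in% .map_header_names) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (nrow(raw) == 0L) {
    stop(what, " contains no entries", call. = FALSE)
  }
  stats::setNames(raw[[2L]], raw[[1L]])
}

#' Read a population map
#'
#' Reads a two-column TSV (`sequence_id <TAB> population`; a header row is
#' autodetected and skipped) and checks it against an alignment: every
#' sequence must be assigned to exactly one population. Map entries for ids
#' absent from the alignment are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param alignment A [hap_alignment] the map must cover.
#' @return A named character vector mapping `sequence_id` to population,
#'   ordered as in the alignment, with attribute `pop_order` giving the
#'   populations in order of first appearance in the map file.
#' @export
read_population_map <- function(path, alignment) {
  stopifnot(inherits(alignment, "hap_alignment"))
  map <- read_two_column_tsv(path, "population map")
  if (anyDuplicated(names(map))) {
    stop("population map assigns some sequence more than once: '",
         names(map)[duplicated(names(map))][1L], "'", call. = FALSE)
  }
  extra <- setdiff(names(map), alignment$ids)
  if (length(extra) > 0L) {
    warning(length(extra), " population-map entr",
            if (length(extra) == 1L) "y" else "ies",
            " not present in the alignment ignored (e.g. '", extra[1L], "')",
            call. = FALSE)
  }
  missing <- setdiff(alignment$ids, names(map))
  if (length(missing) > 0L) {
    stop("population map does not cover the alignment: no population for '",
         missing[1L], "'",
         if (length(missing) > 1L) paste0(" and ", length(missing) - 1L,
                                          " more"),
         call. = FALSE)
  }
  pop_order <- unique(unname(map[names(map) %in% alignment$ids]))
  if (length(pop_order) < 2L) {
    stop("population map must define at least 2 populations", call. = FALSE)
  }
  out <- map[alignment$ids]
  attr(out, "pop_order") <- pop_order
  out
}

#' Read a clade map
#'
#' Reads a two-column TSV assigning haplotype ids (or sequence ids, see
#' [lift_clade_assignment()]) to clade labels.
#'
#' @param path Path to the TSV file.
#' @return A named character vector `id -> clade`.
#' @export
read_clade_map <- function(path) {
  map <- read_two_column_tsv(path, "clade map")
  if (anyDuplicated(names(map))) {
    stop("clade map assigns some id more than once: '",
         names(map)[duplicated(names(map))][1L], "'", call. = FALSE)
  }
  map
}

#' Lift a per-sequence clade assignment to haplotypes
#'
#' Clades are properties of haplotypes; when a clade map is given per
#' sequence it is lifted through the haplotype incidence, requiring all
#' sequences of one haplotype to agree.
#'
#' @param clades Named character vector, `sequence_id -> clade`.
#' @param incidence A [collapse_haplotypes()] result.
#' @return Named character vector `haplotype_id -> clade`.
#' @export
lift_clade_assignment <- function(clades, incidence) {
  stopifnot(inherits(incidence, "hap_incidence"))
  sh <- incidence$sequence_haplotype
  missing <- setdiff(names(sh), names(clades))
  if (length(missing) > 0L) {
    stop("clade map missing sequence '", missing[1L], "'", call. = FALSE)
  }
  out <- vapply(incidence$haplotype_ids, function(h) {
    lab <- unique(clades[names(sh)[sh == h]])
    if (length(lab) != 1L) {
      stop("sequences of haplotype ", h, " carry conflicting clades: ",
           paste(lab, collapse = ", "), call. = FALSE)
    }
    lab
  }, character(1L))
  out
}

# Display precisions matching the conventions of the result tables:
# diversity at 3 (Hd, K) / 5 (Pi) decimals, richness R at 3, rates C% at 4,
# composite scores Fz at 3.
.display_digits <- c(Hd = 3L, Hd_se = 3L, Pi = 5L, K = 3L,
                     R_S = 3L, R_D = 3L, R_T = 3L,
                     C_RS_pct = 4L, C_RD_pct = 4L, C_RT_pct = 4L,
                     Fz = 3L, distance = 3L, fst = 4L, nm = 4L)

#' Round a result table for display
#'
#' Applies the per-column display precisions used throughout the package
#' (Hd and K at 3 decimals, Pi at 5, richness contributions R at 3,
#' contribution rates C% at 4, composite scores at 3). Columns without a
#' registered precision are left untouched.
#'
#' @param x A data frame of results.
#' @return The data frame with display rounding applied.
#' @export
display_table <- function(x) {
  for (nm in intersect(names(x), names(.display_digits))) {
    if (is.numeric(x[[nm]])) {
      x[[nm]] <- round(x[[nm]], .display_digits[[nm]])
    }
  }
  x
}

#' Write a result table to CSV or JSON
#'
#' Numeric values are written at full precision; use [display_table()]
#' first for paper-style rounding. JSON output mirrors the same fields
#' row-wise and round-trips exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}
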