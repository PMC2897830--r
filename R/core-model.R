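#' Create a segment (contiguous residue range)
#'
#' A segment is one contiguous stretch of residues, the unit out of which
#' domain fragments are built.  Residue indices are 1-based sequential
#' positions within the chain, inclusive at both ends.
#'
#' @param start first residue index (>= 1)
#' @param end last residue index (>= start)
#' @return an object of class \code{"segment"}: a list with elements
#'   \code{start} and \code{end}
#' @examples
#' segment(1, 100)
#' @export
segment <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("segment start/end must be single non-missing integers")
  if (start < 1L) stop("segment start must be >= 1, got ", start)
  if (end < start) stop("segment end (", end, ") must be >= start (", start, ")")
  structure(list(start = start, end = end), class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("[%d-%d]", x$start, x$end), "\n")
  invisible(x)
}

seg_length <- function(s) s$end - s$start + 1L

#' Create a domain from one or more fragments
#'
#' A domain is one structural unit of a chain.  Continuous domains have a
#' single fragment; discontinuous domains carry several non-overlapping
#' fragments separated along the sequence.
#'
#' @param domain_id character label for the domain
#' @param fragments a list of \code{\link{segment}} objects, or a single
#'   segment; also accepts a 2-column matrix of (start, end) rows
#' @return an object of class \code{"domain"}
#' @examples
#' domain("D1", list(segment(1, 30), segment(71, 100)))
#' @export
domain <- function(domain_id, fragments) {
  if (inherits(fragments, "segment")) fragments <- list(fragments)
  if (is.matrix(fragments)) {
    fragments <- lapply(seq_len(nrow(fragments)),
                        function(i) segment(fragments[i, 1], fragments[i, 2]))
  }
  if (!is.list(fragments) || length(fragments) == 0L)
    stop("a domain needs at least one fragment")
  ok <- vapply(fragments, inherits, logical(1), what = "segment")
  if (!all(ok)) stop("all fragments must be segment objects")
  structure(list(domain_id = as.character(domain_id), fragments = fragments),
            class = "domain")
}

#' @export
print.domain <- function(x, ...) {
  spans <- vapply(x$fragments, function(s) sprintf("%d-%d", s$start, s$end),
                  character(1))
  cat(sprintf("domain %s: %s\n", x$domain_id, paste(spans, collapse = ",")))
  invisible(x)
}

#' Residue set of a domain
#'
#' Union of all fragment ranges of a domain, inclusive of endpoints.
#'
#' @param d a \code{\link{domain}}
#' @return sorted integer vector of residue indices
#' @examples
#' residue_set(domain("D1", list(segment(1, 5), segment(8, 10))))
#' @export
residue_set <- function(d) {
  stopifnot(inherits(d, "domain"))
  sort(unique(unlist(lapply(d$fragments, function(s) s$start:s$end))))
}

#' Create a chain assignment (one method's partition of a chain)
#'
#' @param pdb_id 4-character PDB identifier (any short label is accepted)
#' @param chain_id single chain label
#' @param method name of the assignment method
#' @param domains list of \code{\link{domain}} objects
#' @param chain_extent a \code{\link{segment}} giving the first and last
#'   assigned residue of the chain; defaults to the min/max residue over the
#'   given domains.  Residues inside the extent but outside every domain are
#'   permitted (some methods leave linkers unassigned).
#' @return an object of class \code{"chain_assignment"}
#' @export
chain_assignment <- function(pdb_id, chain_id, method, domains,
                             chain_extent = NULL) {
  if (inherits(domains, "domain")) domains <- list(domains)
  if (!is.list(domains) || length(domains) == 0L)
    stop("a chain assignment needs at least one domain")
  ok <- vapply(domains, inherits, logical(1), what = "domain")
  if (!all(ok)) stop("all domains must be domain objects")
  if (is.null(chain_extent)) {
    res <- unlist(lapply(domains, residue_set))
    chain_extent <- segment(min(res), max(res))
  }
  a <- structure(list(pdb_id = as.character(pdb_id),
                      chain_id = as.character(chain_id),
                      method = as.character(method),
                      domains = domains,
                      chain_extent = chain_extent),
                 class = "chain_assignment")
  n <- seg_length(chain_extent)
  if (n < 40L)
    warning(sprintf("chain %s%s spans only %d residues; short chains rarely have meaningful domain partitions",
                    a$pdb_id, a$chain_id, n))
  a
}

#' @export
print.chain_assignment <- function(x, ...) {
  cat(sprintf("chain assignment %s%s by %s (%d domain%s, extent %d-%d)\n",
              x$pdb_id, x$chain_id, x$method, length(x$domains),
              if (length(x$domains) == 1L) "" else "s",
              x$chain_extent$start, x$chain_extent$end))
  for (d in x$domains) print(d)
  invisible(x)
}

#' Validate a chain assignment
#'
#' Checks the structural invariants of an assignment and reports every
#' violation found; validation itself never raises.
#'
#' Invariants checked: fragment ranges are well-formed; fragments within a
#' domain do not overlap; domains do not share residues; every domain residue
#' lies within the chain extent.
#'
#' @param a a \code{\link{chain_assignment}} (structure is tolerated even if
#'   built by hand, so malformed objects can be diagnosed)
#' @return character vector of violation messages; empty when valid
#' @export
validate_assignment <- function(a) {
  v <- character(0)
  if (!is.list(a) || is.null(a$domains) || length(a$domains) == 0L)
    return("assignment: no domains")
  for (d in a$domains) {
    for (s in d$fragments) {
      if (s$end < s$start)
        v <- c(v, sprintf("range: domain %s fragment %d-%d has end < start",
                          d$domain_id, s$start, s$end))
      if (s$start < 1L)
        v <- c(v, sprintf("range: domain %s fragment starts at %d (< 1)",
                          d$domain_id, s$start))
    }
    # within-domain fragment overlap
    if (length(d$fragments) > 1L) {
      res <- unlist(lapply(d$fragments, function(s) s$start:s$end))
      if (anyDuplicated(res))
        v <- c(v, sprintf("overlap: domain %s has overlapping fragments",
                          d$domain_id))
    }
  }
  # between-domain overlap
  nd <- length(a$domains)
  if (nd > 1L) {
    sets <- lapply(a$domains, function(d)
      unique(unlist(lapply(d$fragments, function(s) s$start:s$end))))
    for (i in seq_len(nd - 1L)) for (j in (i + 1L):nd) {
      shared <- intersect(sets[[i]], sets[[j]])
      if (length(shared))
        v <- c(v, sprintf("overlap: domains %s and %s share residue %d",
                          a$domains[[i]]$domain_id, a$domains[[j]]$domain_id,
                          min(shared)))
    }
  }
  if (!is.null(a$chain_extent)) {
    for (d in a$domains) for (s in d$fragments) {
      if (s$start < a$chain_extent$start || s$end > a$chain_extent$end)
        v <- c(v, sprintf("extent: domain %s fragment %d-%d outside chain extent %d-%d",
                          d$domain_id, s$start, s$end,
                          a$chain_extent$start, a$chain_extent$end))
    }
  }
  v
}

#' Canonical ordering of a chain assignment
#'
#' Sorts fragments within each domain by start position and domains by the
#' start of their N-terminal fragment.  Downstream domain pairing relies on
#' this ordering being deterministic.  Idempotent.
#'
#' @param a a valid \code{\link{chain_assignment}}
#' @return the reordered assignment
#' @export
canonical_order <- function(a) {
  v <- validate_assignment(a)
  if (length(v)) stop("invalid assignment: ", paste(v, collapse = "; "))
  doms <- lapply(a$domains, function(d) {
    o <- order(vapply(d$fragments, function(s) s$start, integer(1)))
    d$fragments <- d$fragments[o]
    d
  })
  starts <- vapply(doms, function(d) d$fragments[[1]]$start, integer(1))
  # equal starts would mean two domains share a residue, excluded by validation
  stopifnot(!anyDuplicated(starts))
  a$domains <- doms[order(starts)]
  a
}

#' Collect chain assignments into an assignment set
#'
#' An assignment set holds one \code{\link{chain_assignment}} per method for a
#' single (pdb_id, chain_id).
#'
#' @param assignments list of \code{\link{chain_assignment}} objects, all for
#'   the same chain, one per method
#' @return an object of class \code{"assignment_set"} with fields
#'   \code{pdb_id}, \code{chain_id} and \code{assignments} (named by method)
#' @export
assignment_set <- function(assignments) {
  if (inherits(assignments, "chain_assignment"))
    assignments <- list(assignments)
  if (!length(assignments)) stop("assignment set needs at least one method")
  ids <- unique(vapply(assignments, function(a) paste0(a$pdb_id, "|", a$chain_id),
                       character(1)))
  if (length(ids) != 1L)
    stop("all assignments in a set must describe the same chain; got: ",
         paste(ids, collapse = ", "))
  methods <- vapply(assignments, function(a) a$method, character(1))
  if (anyDuplicated(methods))
    stop("duplicate method name in assignment set: ",
         methods[duplicated(methods)][1])
  names(assignments) <- methods
  structure(list(pdb_id = assignments[[1]]$pdb_id,
                 chain_id = assignments[[1]]$chain_id,
                 assignments = assignments),
            class = "assignment_set")
}

#' @export
print.assignment_set <- function(x, ...) {
  cat(sprintf("assignment set %s%s: %d method(s)\n", x$pdb_id, x$chain_id,
              length(x$assignments)))
  for (a in x$assignments) print(a)
  invisible(x)
}

#' Secondary-structure annotation of a chain
#'
#' Builds a per-residue annotation from a one-letter code string or a
#' character vector (DSSP codes: H/G/I helices, E strand, B bridge, T turn,
#' S bend, and \code{"-"}/\code{"C"}/\code{" "} for loop).  Helix elements
#' are maximal runs of H/G/I; strand elements are maximal runs of E.  An
#' isolated bridge (B) does not form a strand run.
#'
#' @param codes single string or character vector of per-residue codes;
#'   residue i corresponds to position i
#' @return an object of class \code{"ss_annotation"}: list with \code{codes}
#'   (character vector) and \code{elements} (data.frame with columns
#'   \code{kind}, \code{start}, \code{end})
#' @examples
#' ss_annotation("HHHHHH--EEEE")
#' @export
ss_annotation <- function(codes) {
  if (length(codes) == 1L && is.character(codes) && nchar(codes) > 1L)
    codes <- strsplit(codes, "")[[1]]
  codes <- as.character(codes)
  codes[codes %in% c(" ", "C", ".")] <- "-"
  kind <- ifelse(codes %in% c("H", "G", "I"), "helix",
                 ifelse(codes == "E", "strand", "loop"))
  elements <- runs_to_elements(kind)
  structure(list(codes = codes, elements = elements), class = "ss_annotation")
}

# maximal runs of helix/strand over a per-residue kind vector
runs_to_elements <- function(kind) {
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("helix", "strand")
  data.frame(kind = r$values[keep], start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.ss_annotation <- function(x, ...) {
  nh <- sum(x$elements$kind == "helix")
  ne <- sum(x$elements$kind == "strand")
  cat(sprintf("secondary structure: %d residues, %d helix element(s), %d strand element(s)\n",
              length(x$codes), nh, ne))
  invisible(x)
}

#' Default parameters for agreement, consensus and boundary analysis
#'
#' @param overlap_threshold minimum bidirectional residue-overlap fraction for
#'   two compared domains (and fragments) to count as agreeing; default 0.80
#' @param consensus_threshold minimum group reliability (percent) required to
#'   declare a consensus; default 40
#' @param near_tie_window when the runner-up group's reliability is strictly
#'   less than this many percentage points below the top group, both groups
#'   are reported; default 10
#' @param helix_end_exclusion residues spared at each helix end when deciding
#'   whether a boundary cuts the helix; default 2
#' @param strand_end_exclusion residues spared at each strand end; default 1
#' @param rule_adjustment fractional weight change applied by each context
#'   rule (0.10 means "reduced by 10\%" multiplies by 0.9); default 0.10
#' @param base_weights named numeric vector of prior-performance weights
#'   (percent correct chains on a balanced multi-domain benchmark)
#' @param method_order order in which methods are considered during greedy
#'   grouping; methods absent from this list are appended alphabetically
#' @param ss_class_minor_fraction tolerated minority fraction when calling a
#'   chain all-alpha or all-beta; default 0.05
#' @param compare_fragments also require the per-fragment overlap criterion
#'   (strictest reading); default TRUE
#' @param pairing domain pairing strategy: \code{"positional"} after canonical
#'   ordering (default, deterministic) or \code{"optimal"} (maximum total
#'   overlap over pairings; for robustness studies)
#' @param dedupe_boundaries collapse boundaries reported by one method at the
#'   same residue to a single boundary; default TRUE
#' @return an object of class \code{"consensus_params"} (a named list)
#' @export
consensus_params <- function(overlap_threshold = 0.80,
                             consensus_threshold = 40,
                             near_tie_window = 10,
                             helix_end_exclusion = 2L,
                             strand_end_exclusion = 1L,
                             rule_adjustment = 0.10,
                             base_weights = c(PDP = 84.4, NCBI = 81.9,
                                              DomainParser2 = 78.1,
                                              DDomain = 76.5, PUU = 74.0,
                                              DHcL = 68.3, Dodis = 40.0),
                             method_order = c("PDP", "DomainParser2", "PUU",
                                              "DDomain", "NCBI", "DHcL",
                                              "Dodis"),
                             ss_class_minor_fraction = 0.05,
                             compare_fragments = TRUE,
                             pairing = c("positional", "optimal"),
                             dedupe_boundaries = TRUE) {
  pairing <- match.arg(pairing)
  if (!(overlap_threshold > 0 && overlap_threshold <= 1))
    stop("overlap_threshold must be in (0, 1]")
  if (consensus_threshold < 0 || consensus_threshold > 100)
    stop("consensus_threshold must be in [0, 100]")
  if (any(base_weights <= 0 | base_weights > 100))
    stop("base weights must be in (0, 100]")
  structure(list(overlap_threshold = overlap_threshold,
                 consensus_threshold = consensus_threshold,
                 near_tie_window = near_tie_window,
                 helix_end_exclusion = as.integer(helix_end_exclusion),
                 strand_end_exclusion = as.integer(strand_end_exclusion),
                 rule_adjustment = rule_adjustment,
                 base_weights = base_weights,
                 method_order = method_order,
                 ss_class_minor_fraction = ss_class_minor_fraction,
                 compare_fragments = compare_fragments,
                 pairing = pairing,
                 dedupe_boundaries = dedupe_boundaries),
            class = "consensus_params")
}

#' Load parameters from a YAML or JSON configuration file
#'
#' Keys present in the file override the built-in defaults; unknown keys are
#' an error.  \code{base_weights} must be a named mapping method -> percent.
#'
#' @param path configuration file (extension .yaml/.yml or .json)
#' @return a \code{\link{consensus_params}} object
#' @export
params_from_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(consensus_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown parameter(s) in config: ",
                        paste(bad, collapse = ", "))
  if (!is.null(cfg$base_weights)) cfg$base_weights <- unlist(cfg$base_weights)
  do.call(consensus_params, cfg)
}
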