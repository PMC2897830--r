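#' Extract domain and fragment boundaries from an assignment
#'
#' Every fragment contributes its start and end residues as boundaries,
#' except positions coinciding with the chain termini (the first and last
#' assigned residue of the chain are not boundaries).  A boundary is tagged
#' \code{domain_start}/\code{domain_end} when it is the N-/C-terminal end of
#' the whole domain, otherwise \code{fragment_start}/\code{fragment_end}.
#' With \code{p$dedupe_boundaries} (the default) boundaries a method reports
#' at the same residue are collapsed to one.
#'
#' @param a a valid \code{\link{chain_assignment}}
#' @param p a \code{\link{consensus_params}} object
#' @return data.frame with columns method, residue, kind, domain_id
#' @examples
#' a <- chain_assignment("1abc", "A", "m", list(
#'   domain("D1", segment(1, 50)), domain("D2", segment(51, 100))))
#' extract_boundaries(a)  # residues 50 and 51
#' @export
extract_boundaries <- function(a, p = consensus_params()) {
  a <- canonical_order(a)
  lo <- a$chain_extent$start
  hi <- a$chain_extent$end
  rows <- list()
  for (d in a$domains) {
    nf <- length(d$fragments)
    for (f in seq_len(nf)) {
      s <- d$fragments[[f]]
      if (s$start != lo)
        rows[[length(rows) + 1L]] <- data.frame(
          method = a$method, residue = s$start,
          kind = if (f == 1L) "domain_start" else "fragment_start",
          domain_id = d$domain_id, stringsAsFactors = FALSE)
      if (s$end != hi)
        rows[[length(rows) + 1L]] <- data.frame(
          method = a$method, residue = s$end,
          kind = if (f == nf) "domain_end" else "fragment_end",
          domain_id = d$domain_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(method = character(0), residue = integer(0),
                      kind = character(0), domain_id = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$residue), , drop = FALSE]
  if (isTRUE(p$dedupe_boundaries))
    out <- out[!duplicated(out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a boundary cut a secondary-structure element?
#'
#' A helix is cut when the boundary falls inside it but not within the first
#' or last \code{helix_end_exclusion} residues (default 2: boundaries at the
#' first, second, penultimate or ultimate helix residue do not split it).  A
#' strand is cut unless the boundary sits on its first or last
#' \code{strand_end_exclusion} residues (default 1).  Elements no longer
#' than twice the exclusion can never be cut.
#'
#' @param residue boundary residue index
#' @param kind \code{"helix"} or \code{"strand"}
#' @param element a \code{\link{segment}} (the element's span)
#' @param p a \code{\link{consensus_params}} object
#' @return logical
#' @export
is_cut <- function(residue, kind, element, p = consensus_params()) {
  excl <- switch(kind, helix = p$helix_end_exclusion,
                 strand = p$strand_end_exclusion,
                 stop("unknown element kind: ", kind))
  residue >= element$start + excl & residue <= element$end - excl
}

trimmed_elements <- function(ss, p) {
  el <- ss$elements
  if (!nrow(el)) return(el)
  excl <- ifelse(el$kind == "helix", p$helix_end_exclusion,
                 p$strand_end_exclusion)
  el$cut_lo <- el$start + excl
  el$cut_hi <- el$end - excl
  el
}

#' Per-method statistics of boundaries cutting secondary structure
#'
#' For every method in the set, counts its boundaries and how many of them
#' cut a helix or a strand element (per the end-exclusion rules of
#' \code{\link{is_cut}}).  A boundary is counted at most once per element
#' kind.  Methods with zero boundaries report fractions of 0 and are
#' flagged.
#'
#' @param S an \code{\link{assignment_set}}
#' @param ss an \code{\link{ss_annotation}} covering the chain
#' @param p a \code{\link{consensus_params}} object
#' @return data.frame with one row per method: method, n_boundaries,
#'   n_helix_cuts, n_strand_cuts, helix_cut_fraction, strand_cut_fraction,
#'   no_boundaries
#' @export
boundary_statistics <- function(S, ss, p = consensus_params()) {
  stopifnot(inherits(S, "assignment_set"), inherits(ss, "ss_annotation"))
  el <- trimmed_elements(ss, p)
  cuts_kind <- function(residues, kind) {
    ek <- el[el$kind == kind, , drop = FALSE]
    if (!nrow(ek)) return(0L)
    sum(vapply(residues, function(r)
      any(r >= ek$cut_lo & r <= ek$cut_hi), logical(1)))
  }
  rows <- lapply(names(S$assignments), function(m) {
    b <- extract_boundaries(S$assignments[[m]], p)
    n <- nrow(b)
    nh <- if (n) cuts_kind(b$residue, "helix") else 0L
    ne <- if (n) cuts_kind(b$residue, "strand") else 0L
    data.frame(method = m, n_boundaries = n, n_helix_cuts = nh,
               n_strand_cuts = ne,
               helix_cut_fraction = if (n) nh / n else 0,
               strand_cut_fraction = if (n) ne / n else 0,
               no_boundaries = n == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-residue text track of structure and boundaries over a range
#'
#' Renders, for a residue range, one line with the secondary-structure
#' elements (\code{H} for helix, \code{E} for strand; actual element spans,
#' without the end-exclusion trimming used for statistics) and one line per
#' method marking its boundary positions with \code{|}.
#'
#' @param S an \code{\link{assignment_set}}
#' @param ss an \code{\link{ss_annotation}} covering the chain
#' @param range a \code{\link{segment}} within the chain
#' @param methods methods to render (default: all in the set)
#' @param p a \code{\link{consensus_params}} object
#' @return character vector of track lines (printed nicely by
#'   \code{cat(..., sep = "\n")})
#' @export
boundary_context <- function(S, ss, range, methods = names(S$assignments),
                             p = consensus_params()) {
  stopifnot(inherits(range, "segment"))
  if (range$start < 1L || range$end > length(ss$codes))
    stop("range ", range$start, "-", range$end,
         " outside chain 1-", length(ss$codes))
  pos <- range$start:range$end
  width <- length(pos)
  ss_track <- rep(".", width)
  for (i in seq_len(nrow(ss$elements))) {
    el <- ss$elements[i, ]
    hit <- pos >= el$start & pos <= el$end
    ss_track[hit] <- if (el$kind == "helix") "H" else "E"
  }
  label_w <- max(nchar(c("SS", methods)), 6L)
  fmt <- function(label, track)
    sprintf("%-*s %s", label_w, label, paste(track, collapse = ""))
  lines <- c(sprintf("%-*s residues %d-%d", label_w, "range", range$start,
                     range$end),
             fmt("SS", ss_track))
  for (m in methods) {
    b <- extract_boundaries(S$assignments[[m]], p)
    track <- rep(".", width)
    track[pos %in% b$residue] <- "|"
    lines <- c(lines, fmt(m, track))
  }
  lines
}

#' Write a per-boundary cut table
#'
#' One row per (method, boundary, overlapping element) combination plus rows
#' for boundaries that touch no element, classified by the end-exclusion cut
#' rules.
#'
#' @param S an \code{\link{assignment_set}}
#' @param ss an \code{\link{ss_annotation}}
#' @param path output TSV (NULL to just return the table)
#' @param p a \code{\link{consensus_params}} object
#' @return data.frame: method, boundary_residue, kind, element_kind,
#'   element_start, element_end, is_cut
#' @export
boundary_cut_table <- function(S, ss, path = NULL, p = consensus_params()) {
  el <- ss$elements
  rows <- list()
  for (m in names(S$assignments)) {
    b <- extract_boundaries(S$assignments[[m]], p)
    for (i in seq_len(nrow(b))) {
      inside <- which(el$start <= b$residue[i] & el$end >= b$residue[i])
      if (!length(inside)) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, boundary_residue = b$residue[i], kind = b$kind[i],
          element_kind = NA_character_, element_start = NA_integer_,
          element_end = NA_integer_, is_cut = FALSE,
          stringsAsFactors = FALSE)
      } else for (j in inside) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, boundary_residue = b$residue[i], kind = b$kind[i],
          element_kind = el$kind[j], element_start = el$start[j],
          element_end = el$end[j],
          is_cut = is_cut(b$residue[i], el$kind[j],
                          segment(el$start[j], el$end[j]), p),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(method = character(0), boundary_residue = integer(0),
                  kind = character(0), element_kind = character(0),
                  element_start = integer(0), element_end = integer(0),
                  is_cut = logical(0))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
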