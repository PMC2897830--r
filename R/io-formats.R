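ASSIGNMENT_COLUMNS <- c("pdb_id", "chain_id", "method", "domain_id",
                        "start", "end")

#' Build assignment sets from a flat assignment table
#'
#' @param tab data.frame with columns pdb_id, chain_id, method, domain_id,
#'   start, end (one fragment per row)
#' @return named list of \code{\link{assignment_set}} objects, one per
#'   "pdb_id chain_id"; the chain extent of every assignment is the min/max
#'   residue over all methods for that chain
#' @export
assignments_from_table <- function(tab) {
  missing <- setdiff(ASSIGNMENT_COLUMNS, names(tab))
  if (length(missing))
    stop("assignment table lacks column(s): ", paste(missing, collapse = ", "))
  if (!nrow(tab)) return(list())
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  chains <- split(tab, paste(tab$pdb_id, tab$chain_id))
  out <- lapply(chains, function(ct) {
    extent <- segment(min(ct$start), max(ct$end))
    per_method <- split(ct, ct$method)
    assigns <- lapply(per_method, function(mt) {
      doms <- lapply(split(mt, factor(mt$domain_id, levels = unique(mt$domain_id))),
                     function(dt) {
        frs <- lapply(seq_len(nrow(dt)),
                      function(i) segment(dt$start[i], dt$end[i]))
        domain(dt$domain_id[1], frs)
      })
      a <- suppressWarnings(
        chain_assignment(mt$pdb_id[1], mt$chain_id[1], mt$method[1],
                         unname(doms), chain_extent = extent))
      v <- validate_assignment(a)
      if (length(v))
        stop(sprintf("invalid assignment for chain %s%s by %s: %s",
                     a$pdb_id, a$chain_id, a$method,
                     paste(v, collapse = "; ")))
      canonical_order(a)
    })
    assignment_set(unname(assigns))
  })
  names(out) <- names(chains)
  out
}

#' Read domain assignments from the native TSV or JSON format
#'
#' The native TSV is tab-separated with a mandatory header row, columns
#' \code{pdb_id, chain_id, method, domain_id, start, end}, one domain
#' fragment per row; lines starting with \code{#} are comments.  The JSON
#' form is an array of objects with the same fields.
#'
#' @param path input file
#' @param format \code{"tsv"} (default) or \code{"json"}
#' @return named list of \code{\link{assignment_set}} objects, one per chain
#' @export
read_assignments <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("assignment file not found: ", path)
  if (format == "json") {
    tab <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.data.frame(tab))
      stop("JSON assignment file must be an array of row objects: ", path)
    return(assignments_from_table(tab))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("empty assignment file: ", path)
  header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(ASSIGNMENT_COLUMNS, header)
  if (length(missing))
    stop("line ", idx[1], ": header lacks column(s): ",
         paste(missing, collapse = ", "))
  rows <- vector("list", length(idx) - 1L)
  for (k in seq_along(rows)) {
    ln <- idx[k + 1L]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header))
      stop("line ", ln, ": expected ", length(header), " fields, got ",
           length(fields))
    row <- stats::setNames(as.list(fields), header)
    s <- suppressWarnings(as.integer(row$start))
    e <- suppressWarnings(as.integer(row$end))
    if (is.na(s) || is.na(e))
      stop("line ", ln, ": non-integer start/end")
    if (e < s)
      stop("line ", ln, ": fragment end (", e, ") before start (", s, ")")
    row$start <- s
    row$end <- e
    rows[[k]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  assignments_from_table(tab[ASSIGNMENT_COLUMNS])
}

assignment_rows <- function(a) {
  a <- canonical_order(a)
  do.call(rbind, lapply(a$domains, function(d)
    data.frame(pdb_id = a$pdb_id, chain_id = a$chain_id, method = a$method,
               domain_id = d$domain_id,
               start = vapply(d$fragments, function(s) s$start, integer(1)),
               end = vapply(d$fragments, function(s) s$end, integer(1)),
               stringsAsFactors = FALSE)))
}

#' Write assignments to the native TSV format
#'
#' @param x a \code{\link{chain_assignment}}, an \code{\link{assignment_set}}
#'   or a list of either
#' @param path output file
#' @return the path, invisibly
#' @export
write_assignments <- function(x, path) {
  if (inherits(x, "chain_assignment") || inherits(x, "assignment_set"))
    x <- list(x)
  assigns <- unlist(lapply(x, function(el) {
    if (inherits(el, "assignment_set")) el$assignments else list(el)
  }), recursive = FALSE)
  tab <- do.call(rbind, lapply(assigns, assignment_rows))
  lines <- c(paste(ASSIGNMENT_COLUMNS, collapse = "\t"),
             apply(tab, 1, function(r) paste(trimws(r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

# One CATH Domall record: "<pdb><chain> Dxx Fxx" then, per domain, a segment
# count followed by (chain, start, ins, chain, end, ins) per segment; trailing
# fragment records "(size)" describe unassigned bits and are skipped.
parse_domall_record <- function(line, lineno) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) < 3L || !grepl("^D\\d+$", tok[2]) || !grepl("^F\\d+$", tok[3]))
    stop("Domall format error at line ", lineno,
         ": expected '<chain> Dnn Fnn ...', got: ", line)
  chain_name <- tok[1]
  if (nchar(chain_name) < 5L)
    stop("Domall format error at line ", lineno,
         ": chain field '", chain_name, "' shorter than 5 characters")
  pdb_id <- substr(chain_name, 1, 4)
  chain_id <- substr(chain_name, 5, 5)
  ndom <- as.integer(sub("^D", "", tok[2]))
  i <- 4L
  has_ins <- FALSE
  doms <- vector("list", ndom)
  for (d in seq_len(ndom)) {
    nseg <- suppressWarnings(as.integer(tok[i]))
    if (is.na(nseg) || nseg < 1L)
      stop("Domall format error at line ", lineno,
           ": bad segment count '", tok[i], "' for domain ", d)
    i <- i + 1L
    segs <- vector("list", nseg)
    for (s in seq_len(nseg)) {
      if (i + 5L > length(tok) + 1L)
        stop("Domall format error at line ", lineno,
             ": truncated segment record in domain ", d)
      st <- suppressWarnings(as.integer(tok[i + 1L]))
      en <- suppressWarnings(as.integer(tok[i + 4L]))
      if (is.na(st) || is.na(en))
        stop("Domall format error at line ", lineno,
             ": non-numeric segment boundary in domain ", d)
      if (tok[i + 2L] != "-" || tok[i + 5L] != "-") has_ins <- TRUE
      segs[[s]] <- c(st, en)
      i <- i + 6L
    }
    doms[[d]] <- segs
  }
  list(pdb_id = pdb_id, chain_id = chain_id, domains = doms,
       has_insertion_codes = has_ins)
}

#' Read a CATH Domall file as an assignment table
#'
#' Parses the fixed-field CATH Domall v3.x records (read-only).  Each record
#' becomes a set of rows with method \code{"CATH"}.  Author residue numbers
#' are used as sequential indices; when a record starts below residue 1 the
#' whole chain is shifted so its first residue is 1 (the offset is kept in
#' the \code{"offset"} attribute).  Insertion-coded boundaries keep their
#' numeric part; a warning flags the affected records.  Trailing fragment
#' records (unassigned bits, in parentheses) are skipped, as are comment and
#' blank lines.
#'
#' @param path Domall file
#' @return data.frame with columns pdb_id, chain_id, method, domain_id,
#'   start, end, suitable for \code{\link{assignments_from_table}}
#' @export
read_cath_domall <- function(path) {
  if (!file.exists(path)) stop("Domall file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  recs <- lapply(keep, function(ln) parse_domall_record(lines[ln], ln))
  if (!length(recs))
    return(data.frame(pdb_id = character(0), chain_id = character(0),
                      method = character(0), domain_id = character(0),
                      start = integer(0), end = integer(0)))
  if (any(vapply(recs, `[[`, logical(1), "has_insertion_codes")))
    warning("insertion codes present in Domall record(s); numeric residue numbers used")
  offsets <- list()
  rows <- do.call(rbind, lapply(recs, function(r) {
    all_pts <- unlist(r$domains)
    off <- if (min(all_pts) < 1L) 1L - min(all_pts) else 0L
    if (off != 0L)
      offsets[[paste0(r$pdb_id, r$chain_id)]] <<- off
    do.call(rbind, lapply(seq_along(r$domains), function(d) {
      segs <- r$domains[[d]]
      data.frame(pdb_id = r$pdb_id, chain_id = r$chain_id, method = "CATH",
                 domain_id = sprintf("D%02d", d),
                 start = vapply(segs, `[`, numeric(1), 1) + off,
                 end = vapply(segs, `[`, numeric(1), 2) + off,
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$start <- as.integer(rows$start)
  rows$end <- as.integer(rows$end)
  attr(rows, "offset") <- offsets
  rows
}

split_elements_at_breaks <- function(elements, breaks) {
  if (!length(breaks) || !nrow(elements)) return(elements)
  out <- list()
  for (i in seq_len(nrow(elements))) {
    s <- elements$start[i]; e <- elements$end[i]
    cuts <- sort(breaks[breaks >= s & breaks < e])
    bounds <- c(s, cuts + 1L)
    ends <- c(cuts, e)
    for (k in seq_along(bounds))
      out[[length(out) + 1L]] <- data.frame(kind = elements$kind[i],
                                            start = bounds[k], end = ends[k],
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read per-residue secondary structure from classic DSSP output
#'
#' Extracts the summary secondary-structure column (position 17) of each
#' residue record, per chain.  Residues are renumbered sequentially within
#' each chain in file order (author numbering and insertion codes are thereby
#' flattened).  Helix elements are maximal runs of H/G/I, strand elements
#' maximal runs of E; chain-break records (\code{!}) terminate elements.
#'
#' @param path DSSP file
#' @return named list of \code{\link{ss_annotation}} objects, one per chain
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr))
    stop("not a classic DSSP file (missing '  #  RESIDUE' header): ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  chains <- list()   # per chain: list(codes = chr, breaks = int)
  last_chain <- NULL
  for (ln in body) {
    if (nchar(ln) < 17L)
      stop("truncated DSSP record: '", ln, "'")
    aa <- substr(ln, 14, 14)
    ch <- substr(ln, 12, 12)
    if (aa == "!") {
      # break within the current chain; between-chain breaks need no action
      if (!is.null(last_chain) && length(chains[[last_chain]]$codes))
        chains[[last_chain]]$breaks <-
          c(chains[[last_chain]]$breaks, length(chains[[last_chain]]$codes))
      next
    }
    if (is.null(chains[[ch]])) chains[[ch]] <- list(codes = character(0),
                                                    breaks = integer(0))
    chains[[ch]]$codes <- c(chains[[ch]]$codes, substr(ln, 17, 17))
    last_chain <- ch
  }
  if (!length(chains)) stop("DSSP file has no residue records: ", path)
  lapply(chains, function(cc) {
    ann <- ss_annotation(cc$codes)
    ann$elements <- split_elements_at_breaks(ann$elements, cc$breaks)
    ann
  })
}

#' Write a minimal classic-format DSSP file
#'
#' Emits only the columns the reader consumes (residue number, chain,
#' amino-acid placeholder, secondary-structure code) in classic DSSP layout;
#' intended for fixtures and for the simulator's output.
#'
#' @param ss an \code{\link{ss_annotation}} or a named list of them (names =
#'   chain ids)
#' @param path output file
#' @param pdb_id identifier written into the header
#' @return the path, invisibly
#' @export
write_dssp <- function(ss, path, pdb_id = "XXXX") {
  if (inherits(ss, "ss_annotation")) ss <- list(A = ss)
  lines <- c(
    "==== Secondary Structure Definition, minimal writer ====",
    sprintf("HEADER    SYNTHETIC                               01-JAN-00   %s", pdb_id),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  n <- 0L
  for (ch in names(ss)) {
    codes <- ss[[ch]]$codes
    codes[codes == "-"] <- " "
    for (i in seq_along(codes)) {
      n <- n + 1L
      lines <- c(lines, sprintf("%5d%5d %s %s  %s", n, i, ch, "A", codes[i]))
    }
    if (ch != names(ss)[length(ss)]) {
      n <- n + 1L
      lines <- c(lines, sprintf("%5d        !*             ", n))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

params_to_list <- function(p) {
  out <- unclass(p)
  out$base_weights <- as.list(out$base_weights)
  out
}

result_to_list <- function(result, assignments = NULL) {
  groups <- lapply(result$groups, function(g) {
    entry <- list(members = as.list(g$members),
                  representative = g$representative,
                  reliability = g$reliability)
    if (!is.null(assignments)) {
      rep_a <- canonical_order(assignments$assignments[[g$representative]])
      entry$domains <- lapply(rep_a$domains, function(d)
        list(id = d$domain_id,
             fragments = lapply(d$fragments, function(s) c(s$start, s$end))))
    }
    entry
  })
  list(pdb_id = result$pdb_id, chain_id = result$chain_id,
       mode = result$mode,
       parameters = params_to_list(result$parameters),
       groups = groups,
       consensus = as.list(as.integer(result$consensus)),
       status = result$status,
       runner_up_below_threshold = isTRUE(result$runner_up_below_threshold))
}

#' Write a consensus report
#'
#' Serializes a consensus result: each group's members, its representative's
#' domain boundaries, the reliability score, the status and the parameter
#' values used.  The JSON form round-trips losslessly via
#' \code{\link{read_consensus_report}}.
#'
#' @param result a \code{"consensus_result"} from
#'   \code{\link{simple_consensus}} or \code{\link{weighted_consensus}}
#' @param assignments the \code{\link{assignment_set}} the result was
#'   computed from (supplies the representatives' boundaries); may be NULL
#' @param path output file
#' @param format \code{"json"}, \code{"tsv"} or \code{"text"}
#' @return the path, invisibly
#' @export
write_consensus_report <- function(result, assignments = NULL, path,
                                   format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "consensus_result"))
  if (format == "json") {
    jsonlite::write_json(result_to_list(result, assignments), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (format == "tsv") {
    rows <- vapply(seq_along(result$groups), function(g) {
      grp <- result$groups[[g]]
      paste(c(g, paste(grp$members, collapse = ","), grp$representative,
              format(grp$reliability, digits = 15),
              as.integer(g %in% result$consensus)), collapse = "\t")
    }, character(1))
    writeLines(c(sprintf("# %s consensus %s%s status=%s", result$mode,
                         result$pdb_id, result$chain_id, result$status),
                 "group\tmembers\trepresentative\treliability\tin_consensus",
                 rows), path)
  } else {
    con <- file(path, "w")
    sink(con)
    on.exit({ sink(); close(con) })
    print(result)
  }
  invisible(path)
}

#' Read back a JSON consensus report
#'
#' @param path file written by \code{\link{write_consensus_report}} with
#'   \code{format = "json"}
#' @return the report as a list (schema: pdb_id, chain_id, mode, parameters,
#'   groups, consensus, status)
#' @export
read_consensus_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
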