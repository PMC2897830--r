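#' Greedy grouping of methods by pairwise agreement
#'
#' Methods are processed in \code{p$method_order} (methods not listed are
#' appended alphabetically).  The first method founds group 1 and becomes its
#' representative.  Each subsequent method is compared against the
#' representative of every existing group in creation order and joins the
#' first group whose representative it agrees with
#' (\code{\link{assignments_agree}}); if it agrees with none it founds a new
#' group with itself as representative.
#'
#' Because pairwise agreement is not transitive, the outcome can depend on
#' the processing order in borderline cases; the fixed method order makes the
#' result deterministic.
#'
#' @param S an \code{\link{assignment_set}}
#' @param p a \code{\link{consensus_params}} object
#' @return list of groups, each a list with \code{members} (character
#'   vector), \code{representative} (founding method)
#' @export
group_methods <- function(S, p = consensus_params()) {
  stopifnot(inherits(S, "assignment_set"))
  methods <- names(S$assignments)
  if (!length(methods)) stop("empty assignment set")
  ordered <- c(intersect(p$method_order, methods),
               sort(setdiff(methods, p$method_order)))
  groups <- list()
  for (m in ordered) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      rep_m <- groups[[g]]$representative
      if (assignments_agree(S$assignments[[m]], S$assignments[[rep_m]], p)) {
        groups[[g]]$members <- c(groups[[g]]$members, m)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      groups[[length(groups) + 1L]] <- list(members = m, representative = m)
  }
  groups
}

# shared threshold / near-tie / status logic for both consensus modes.
# reliabilities: numeric vector per group, in group-creation order.
decide_consensus <- function(groups, reliabilities, p) {
  for (g in seq_along(groups)) groups[[g]]$reliability <- reliabilities[g]
  # ties in reliability resolved by earlier creation order (stable sort)
  ranked <- order(-reliabilities)
  top <- ranked[1]
  if (reliabilities[top] >= p$consensus_threshold) {
    if (length(ranked) >= 2L &&
        reliabilities[top] - reliabilities[ranked[2]] < p$near_tie_window) {
      consensus <- ranked[1:2]
      status <- "tied_consensus"
    } else {
      consensus <- top
      status <- "consensus"
    }
  } else {
    consensus <- integer(0)
    status <- "no_consensus"
  }
  runner_below <- status == "tied_consensus" &&
    reliabilities[ranked[2]] < p$consensus_threshold
  list(groups = groups, consensus = consensus, status = status,
       runner_up_below_threshold = runner_below)
}

#' Simple (equal-vote) consensus of a multi-method assignment set
#'
#' Groups agreeing methods (\code{\link{group_methods}}) and scores each
#' group by the percentage of contributing methods:
#' reliability = 100 * |members| / |methods|.  The highest-scoring group is
#' reported as the consensus if its reliability reaches
#' \code{p$consensus_threshold} (default 40\%); when a runner-up group scores
#' strictly less than \code{p$near_tie_window} (default 10) percentage points
#' below the top group, both are reported (\code{tied_consensus}).  If no
#' group reaches the threshold, no consensus is reported.
#'
#' @param S an \code{\link{assignment_set}}
#' @param p a \code{\link{consensus_params}} object
#' @return an object of class \code{"consensus_result"}: list with
#'   \code{groups} (each with members, representative, reliability),
#'   \code{consensus} (indices of 0--2 reported groups, best first),
#'   \code{mode}, \code{status} and the parameters used
#' @export
simple_consensus <- function(S, p = consensus_params()) {
  groups <- group_methods(S, p)
  n <- length(S$assignments)
  rel <- vapply(groups, function(g) 100 * length(g$members) / n, numeric(1))
  out <- decide_consensus(groups, rel, p)
  structure(c(out, list(mode = "simple", pdb_id = S$pdb_id,
                        chain_id = S$chain_id, n_methods = n,
                        parameters = p)),
            class = "consensus_result")
}

#' Coarse structure class of a chain from its secondary structure
#'
#' Fractions are computed among residues belonging to a helix or strand
#' element.  A chain is \code{all_alpha} when the strand fraction does not
#' exceed \code{p$ss_class_minor_fraction} (default 0.05), \code{all_beta}
#' symmetrically, \code{irregular} when no element residues exist, and
#' \code{alpha_beta} otherwise.
#'
#' @param ss an \code{\link{ss_annotation}}
#' @param p a \code{\link{consensus_params}} object
#' @return one of \code{"all_alpha"}, \code{"all_beta"}, \code{"alpha_beta"},
#'   \code{"irregular"}
#' @export
classify_structure <- function(ss, p = consensus_params()) {
  stopifnot(inherits(ss, "ss_annotation"))
  if (!length(ss$codes)) stop("empty secondary-structure annotation")
  el <- ss$elements
  n_helix <- sum(ifelse(el$kind == "helix", el$end - el$start + 1L, 0L))
  n_strand <- sum(ifelse(el$kind == "strand", el$end - el$start + 1L, 0L))
  tot <- n_helix + n_strand
  if (tot == 0L) return("irregular")
  h <- n_helix / tot
  e <- n_strand / tot
  if (e <= p$ss_class_minor_fraction && h > 0) return("all_alpha")
  if (h <= p$ss_class_minor_fraction && e > 0) return("all_beta")
  "alpha_beta"
}

n_domains_of <- function(S, m) length(S$assignments[[m]]$domains)
has_fragmented <- function(S, m)
  any(vapply(S$assignments[[m]]$domains,
             function(d) length(d$fragments) > 1L, logical(1)))

#' Context rules adjusting method weights for the weighted consensus
#'
#' Starting from the prior-performance base weights, nine context rules are
#' applied in fixed order; each applicable rule multiplies the affected
#' method's weight by (1 - \code{rule_adjustment}) for a reduction or
#' (1 + \code{rule_adjustment}) for an increase (default: times 0.9 / 1.1).
#' The rules look at predicted domain counts, domain fragmentation, and the
#' chain's structure class:
#' \enumerate{
#'   \item PDP and NCBI both predict >= 4 domains: reduce DomainParser2.
#'   \item PUU predicts more domains than both PDP and NCBI: reduce PUU.
#'   \item PDP predicts >= 5 domains: reduce NCBI.
#'   \item >= 3 methods have a fragmented domain: reduce every method with
#'     no fragmented domain.
#'   \item Neither NCBI nor PDP has a fragmented domain: reduce every method
#'     that predicts fragmented domains.
#'   \item All-alpha chain and PDP/NCBI disagree on the domain count:
#'     increase PDP.
#'   \item All-beta chain and PDP/NCBI disagree on the count: increase PDP.
#'   \item All-beta chain and PDP/NCBI agree on the count: increase both.
#'   \item Alpha-beta chain and PDP/NCBI agree on the count: reduce every
#'     method not in PDP's agreement group.
#' }
#' Rules referencing absent methods are skipped.  A method present in the
#' set but missing from \code{base_weights} gets weight 50 with a warning.
#'
#' @param S an \code{\link{assignment_set}}
#' @param cls structure class as returned by \code{\link{classify_structure}}
#' @param groups agreement groups from \code{\link{group_methods}} (used by
#'   rule 9)
#' @param p a \code{\link{consensus_params}} object
#' @return list with \code{weights} (named numeric, adjusted percent) and
#'   \code{provenance} (named list of applied rule ids per method)
#' @export
apply_weight_rules <- function(S, cls, groups, p = consensus_params()) {
  methods <- names(S$assignments)
  w <- p$base_weights[methods]
  names(w) <- methods
  if (anyNA(w)) {
    missing <- methods[is.na(w)]
    warning("no base weight for method(s) ", paste(missing, collapse = ", "),
            "; using 50")
    w[missing] <- 50
  }
  prov <- stats::setNames(vector("list", length(methods)), methods)
  down <- 1 - p$rule_adjustment
  up <- 1 + p$rule_adjustment
  adjust <- function(targets, factor, rule) {
    targets <- intersect(targets, methods)
    for (m in targets) {
      w[m] <<- w[m] * factor
      prov[[m]] <<- c(prov[[m]], rule)
    }
  }
  have <- function(...) all(c(...) %in% methods)

  nd <- stats::setNames(vapply(methods, n_domains_of, integer(1), S = S),
                        methods)
  frag <- stats::setNames(vapply(methods, has_fragmented, logical(1), S = S),
                          methods)

  if (have("PDP", "NCBI", "DomainParser2") &&
      nd["PDP"] >= 4 && nd["NCBI"] >= 4)
    adjust("DomainParser2", down, "R1")
  if (have("PUU", "PDP", "NCBI") &&
      nd["PUU"] > nd["PDP"] && nd["PUU"] > nd["NCBI"])
    adjust("PUU", down, "R2")
  if (have("PDP", "NCBI") && nd["PDP"] >= 5)
    adjust("NCBI", down, "R3")
  if (sum(frag) >= 3)
    adjust(methods[!frag], down, "R4")
  if (have("PDP", "NCBI") && !frag["PDP"] && !frag["NCBI"])
    adjust(methods[frag], down, "R5")
  if (have("PDP", "NCBI")) {
    counts_equal <- nd["PDP"] == nd["NCBI"]
    if (cls == "all_alpha" && !counts_equal) adjust("PDP", up, "R6")
    if (cls == "all_beta" && !counts_equal) adjust("PDP", up, "R7")
    if (cls == "all_beta" && counts_equal) adjust(c("PDP", "NCBI"), up, "R8")
    if (cls == "alpha_beta" && counts_equal) {
      pdp_group <- Filter(function(g) "PDP" %in% g$members, groups)[[1]]
      adjust(setdiff(methods, pdp_group$members), down, "R9")
    }
  }
  list(weights = w, provenance = prov)
}

#' Weighted consensus of a multi-method assignment set
#'
#' Groups methods exactly as \code{\link{simple_consensus}} does, but scores
#' each group by the normalized sum of its members' adjusted weights:
#' reliability = 100 * sum(weights of members) / sum(weights of all methods
#' present).  Weights start from the prior-performance base weights and are
#' adjusted by the context rules (\code{\link{apply_weight_rules}}), which
#' require the chain's secondary structure.  Threshold, near-tie and status
#' logic are identical to the simple mode; with equal weights the weighted
#' reliability reduces exactly to the simple one.
#'
#' @param S an \code{\link{assignment_set}}
#' @param ss an \code{\link{ss_annotation}} covering the chain
#' @param p a \code{\link{consensus_params}} object
#' @return a \code{"consensus_result"} (see \code{\link{simple_consensus}})
#'   with additional fields \code{weights}, \code{weight_provenance} and
#'   \code{structure_class}
#' @export
weighted_consensus <- function(S, ss, p = consensus_params()) {
  stopifnot(inherits(ss, "ss_annotation"))
  groups <- group_methods(S, p)
  cls <- classify_structure(ss, p)
  wr <- apply_weight_rules(S, cls, groups, p)
  total <- sum(wr$weights)
  rel <- vapply(groups, function(g) 100 * sum(wr$weights[g$members]) / total,
                numeric(1))
  out <- decide_consensus(groups, rel, p)
  structure(c(out, list(mode = "weighted", pdb_id = S$pdb_id,
                        chain_id = S$chain_id,
                        n_methods = length(S$assignments),
                        weights = wr$weights,
                        weight_provenance = wr$provenance,
                        structure_class = cls,
                        parameters = p)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("%s consensus for %s%s (%d methods): %s\n",
              x$mode, x$pdb_id, x$chain_id, x$n_methods, x$status))
  for (g in seq_along(x$groups)) {
    grp <- x$groups[[g]]
    tag <- if (g %in% x$consensus) " *" else ""
    cat(sprintf("  group %d (rep %s, reliability %.1f%%): %s%s\n",
                g, grp$representative, grp$reliability,
                paste(grp$members, collapse = ", "), tag))
  }
  if (!is.null(x$structure_class))
    cat(sprintf("  structure class: %s\n", x$structure_class))
  if (isTRUE(x$runner_up_below_threshold))
    cat("  note: tied runner-up group is below the consensus threshold\n")
  invisible(x)
}
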