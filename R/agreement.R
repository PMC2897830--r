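#' Bidirectional overlap fractions of two residue sets
#'
#' @param a,b non-empty integer vectors of residue indices
#' @return numeric length-2 vector: (|a&b|/|a|, |a&b|/|b|)
#' @examples
#' overlap_fractions(1:100, 11:100)  # 0.90, 1.00
#' @export
overlap_fractions <- function(a, b) {
  if (!length(a) || !length(b)) stop("overlap_fractions: empty residue set")
  i <- length(intersect(a, b))
  c(i / length(unique(a)), i / length(unique(b)))
}

# optimal pairing by total intersection; exhaustive over permutations.
# domain counts in practice are tiny (<= 8); beyond that fall back to
# positional pairing with a warning.
optimal_pairing <- function(sets_a, sets_b) {
  n <- length(sets_a)
  if (n > 8L) {
    warning("optimal pairing limited to 8 domains; using positional pairing")
    return(seq_len(n))
  }
  inter <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    length(intersect(sets_a[[i]], sets_b[[j]]))))
  perms <- all_permutations(n)
  scores <- vapply(perms, function(p) sum(inter[cbind(seq_len(n), p)]),
                   numeric(1))
  perms[[which.max(scores)]]
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (k in seq_len(n)) {
    q <- append(p, n, after = k - 1L)
    out[[length(out) + 1L]] <- q
  }
  out
}

#' Pair up the domains of two assignments of the same chain
#'
#' Agreement between two methods first requires that they assign the same
#' number of domains, and the same number of fragments for each matched
#' domain.  Pairing is positional after canonical ordering (the i-th domain
#' by N-terminal start in A pairs with the i-th in B); set
#' \code{pairing = "optimal"} in the parameters for maximum-overlap pairing.
#'
#' @param A,B valid \code{\link{chain_assignment}} objects for the same chain
#' @param p a \code{\link{consensus_params}} object
#' @return \code{NULL} when the assignments cannot match (different domain
#'   counts, or a matched pair with different fragment counts); otherwise a
#'   list with \code{pairs} (2-column matrix of domain indices into the
#'   canonically ordered A and B) and \code{per_pair_overlap} (matrix of the
#'   two overlap fractions per pair)
#' @export
match_domains <- function(A, B, p = consensus_params()) {
  if (A$pdb_id != B$pdb_id || A$chain_id != B$chain_id)
    stop("match_domains: assignments describe different chains (",
         A$pdb_id, A$chain_id, " vs ", B$pdb_id, B$chain_id, ")")
  A <- canonical_order(A)
  B <- canonical_order(B)
  n <- length(A$domains)
  if (n != length(B$domains)) return(NULL)
  sets_a <- lapply(A$domains, residue_set)
  sets_b <- lapply(B$domains, residue_set)
  jb <- if (p$pairing == "optimal") optimal_pairing(sets_a, sets_b)
        else seq_len(n)
  nfrag_a <- vapply(A$domains, function(d) length(d$fragments), integer(1))
  nfrag_b <- vapply(B$domains, function(d) length(d$fragments), integer(1))
  if (any(nfrag_a != nfrag_b[jb])) return(NULL)
  ov <- t(vapply(seq_len(n), function(i)
    overlap_fractions(sets_a[[i]], sets_b[[jb[i]]]), numeric(2)))
  colnames(ov) <- c("frac_a", "frac_b")
  list(pairs = cbind(a = seq_len(n), b = jb), per_pair_overlap = ov,
       A = A, B = B)
}

#' Do two methods agree on the partition of a chain?
#'
#' Two assignments agree when they have the same number of domains and of
#' fragments per matched domain, and the residue overlap between every
#' matched domain (and, by default, every positionally matched fragment
#' within it) covers at least \code{p$overlap_threshold} of EACH partner's
#' residues.  The criterion is symmetric in A and B.
#'
#' @param A,B valid \code{\link{chain_assignment}} objects for the same chain
#' @param p a \code{\link{consensus_params}} object
#' @return logical
#' @examples
#' A <- chain_assignment("1abc", "A", "m1", domain("D1", segment(1, 100)))
#' B <- chain_assignment("1abc", "A", "m2", domain("D1", segment(11, 100)),
#'                       chain_extent = segment(1, 100))
#' assignments_agree(A, B)  # TRUE: fractions 0.90 and 1.00
#' @export
assignments_agree <- function(A, B, p = consensus_params()) {
  m <- match_domains(A, B, p)
  if (is.null(m)) return(FALSE)
  if (any(m$per_pair_overlap < p$overlap_threshold)) return(FALSE)
  if (isTRUE(p$compare_fragments)) {
    for (k in seq_len(nrow(m$pairs))) {
      fa <- m$A$domains[[m$pairs[k, "a"]]]$fragments
      fb <- m$B$domains[[m$pairs[k, "b"]]]$fragments
      for (f in seq_along(fa)) {
        ov <- overlap_fractions(fa[[f]]$start:fa[[f]]$end,
                                fb[[f]]$start:fb[[f]]$end)
        if (any(ov < p$overlap_threshold)) return(FALSE)
      }
    }
  }
  TRUE
}
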