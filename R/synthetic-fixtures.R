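# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  } else assign(".Random.seed", old, envir = env))
  set.seed(seed)
  force(code)
}

# deterministic stream per (seed, method name), independent of iteration order
derive_seed <- function(seed, method_name) {
  M <- 2147483647
  h <- as.numeric(seed) %% M
  for (code in utf8ToInt(method_name)) h <- (h * 31 + code) %% M
  as.integer(h)
}

#' Generate a true (planted) domain partition of a chain
#'
#' Produces contiguous, exhaustive, non-overlapping domains covering
#' residues 1..length, each at least 20 residues long; the division points
#' are random but deterministic for a fixed seed.
#'
#' @param length chain length in residues (>= 20 * n_domains)
#' @param n_domains number of domains (>= 1)
#' @param seed integer seed
#' @param method label for the resulting assignment (default "truth")
#' @return a \code{\link{chain_assignment}}
#' @export
generate_true_partition <- function(length, n_domains, seed,
                                    method = "truth") {
  length <- as.integer(length)
  n_domains <- as.integer(n_domains)
  if (n_domains < 1L) stop("n_domains must be >= 1")
  min_len <- 20L
  if (length < min_len * n_domains)
    stop("chain of ", length, " residues cannot hold ", n_domains,
         " domains of >= ", min_len, " residues")
  lens <- with_seed(seed, {
    extra <- length - min_len * n_domains
    cuts <- if (n_domains > 1L) sort(sample(0:extra, n_domains - 1L,
                                            replace = TRUE)) else integer(0)
    min_len + diff(c(0L, cuts, extra))
  })
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  doms <- lapply(seq_len(n_domains), function(i)
    domain(sprintf("D%02d", i), segment(starts[i], ends[i])))
  suppressWarnings(
    chain_assignment("synt", "A", method, doms,
                     chain_extent = segment(1L, length)))
}

#' Specify how a synthetic method perturbs the true partition
#'
#' The spec emulates the tendencies of real assignment methods: jittering
#' boundary placement, under-cutting (merging adjacent domains), over-cutting
#' (splitting a domain), and fragmenting a domain.
#'
#' @param boundary_jitter maximum boundary shift in residues (>= 0)
#' @param merge_prob probability of merging one adjacent domain pair
#' @param split_prob probability of splitting one domain in two
#' @param fragment_prob probability of fragmenting one domain (its middle
#'   stretch is handed to a neighbouring domain, or left unassigned for a
#'   single-domain chain)
#' @param seed integer seed; combined with the method name to give each
#'   method its own reproducible random stream
#' @return an object of class \code{"perturbation_spec"}
#' @export
perturbation_spec <- function(boundary_jitter = 0L, merge_prob = 0,
                              split_prob = 0, fragment_prob = 0, seed = 0L) {
  probs <- c(merge_prob, split_prob, fragment_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (boundary_jitter < 0) stop("boundary_jitter must be >= 0")
  structure(list(boundary_jitter = as.integer(boundary_jitter),
                 merge_prob = merge_prob, split_prob = split_prob,
                 fragment_prob = fragment_prob, seed = as.integer(seed)),
            class = "perturbation_spec")
}

# contiguous (single-fragment, coverage-complete) view of a valid assignment
domain_spans <- function(a) {
  a <- canonical_order(a)
  t(vapply(a$domains, function(d)
    c(d$fragments[[1]]$start, d$fragments[[length(d$fragments)]]$end),
    integer(2)))
}

perturb_once <- function(truth, spec) {
  spans <- domain_spans(truth)
  min_piece <- 5L
  # jitter internal boundaries
  j <- spec$boundary_jitter
  if (j > 0L && nrow(spans) > 1L) {
    for (i in seq_len(nrow(spans) - 1L)) {
      delta <- sample(seq(-j, j), 1L)
      lo <- spans[i, 1] + min_piece - 1L      # new end of domain i >= this
      hi <- spans[i + 1L, 2] - min_piece      # and <= this
      new_end <- min(max(spans[i, 2] + delta, lo), hi)
      spans[i, 2] <- new_end
      spans[i + 1L, 1] <- new_end + 1L
    }
  }
  if (nrow(spans) > 1L && stats::runif(1) < spec$merge_prob) {
    i <- sample(nrow(spans) - 1L, 1L)
    spans[i, 2] <- spans[i + 1L, 2]
    spans <- spans[-(i + 1L), , drop = FALSE]
  }
  if (stats::runif(1) < spec$split_prob) {
    wide <- which(spans[, 2] - spans[, 1] + 1L >= 2L * min_piece)
    if (length(wide)) {
      i <- wide[sample(length(wide), 1L)]
      at <- sample((spans[i, 1] + min_piece - 1L):(spans[i, 2] - min_piece),
                   1L)
      spans <- rbind(spans[seq_len(i - 1L), , drop = FALSE],
                     c(spans[i, 1], at), c(at + 1L, spans[i, 2]),
                     spans[-seq_len(i), , drop = FALSE])
    }
  }
  doms <- lapply(seq_len(nrow(spans)), function(i)
    domain(sprintf("D%02d", i), segment(spans[i, 1], spans[i, 2])))
  if (stats::runif(1) < spec$fragment_prob) {
    lens <- spans[, 2] - spans[, 1] + 1L
    wide <- which(lens >= 3L * min_piece)
    if (length(wide)) {
      i <- wide[sample(length(wide), 1L)]
      gap_s <- sample((spans[i, 1] + min_piece):(spans[i, 2] - 2L * min_piece + 1L), 1L)
      gap_e <- gap_s + min_piece - 1L
      doms[[i]] <- domain(doms[[i]]$domain_id,
                          list(segment(spans[i, 1], gap_s - 1L),
                               segment(gap_e + 1L, spans[i, 2])))
      nb <- if (i > 1L) i - 1L else if (nrow(spans) > 1L) i + 1L else NA
      if (!is.na(nb))  # hand the gap to a neighbouring domain
        doms[[nb]] <- domain(doms[[nb]]$domain_id,
                             c(doms[[nb]]$fragments,
                               list(segment(gap_s, gap_e))))
      # single-domain chain: the gap stays unassigned (a linker)
    }
  }
  suppressWarnings(
    chain_assignment(truth$pdb_id, truth$chain_id, truth$method, doms,
                     chain_extent = truth$chain_extent))
}

#' Perturb a true partition as one synthetic method would
#'
#' Applies, in order: boundary jitter, a possible merge of one adjacent
#' domain pair, a possible split of one domain, and a possible fragmentation
#' (see \code{\link{perturbation_spec}}).  The random stream is derived from
#' (spec seed, method name) so results do not depend on the order in which
#' methods are generated.  If 100 attempts fail to produce a valid
#' assignment the truth is returned with a warning.
#'
#' @param truth a valid \code{\link{chain_assignment}} with contiguous
#'   domains (e.g. from \code{\link{generate_true_partition}})
#' @param spec a \code{\link{perturbation_spec}}
#' @param method_name name given to the perturbed assignment
#' @return a valid \code{\link{chain_assignment}}
#' @export
perturb <- function(truth, spec, method_name) {
  stopifnot(inherits(spec, "perturbation_spec"))
  truth$method <- method_name
  with_seed(derive_seed(spec$seed, method_name), {
    for (attempt in seq_len(100L)) {
      cand <- tryCatch(perturb_once(truth, spec), error = function(e) NULL)
      if (!is.null(cand) && !length(validate_assignment(cand)))
        return(canonical_order(cand))
    }
    warning("perturb: no valid perturbation found in 100 attempts for ",
            method_name, "; returning the unperturbed truth")
    canonical_order(truth)
  })
}

#' Generate an assignment set of perturbed methods
#'
#' @param truth a \code{\link{chain_assignment}} (the planted partition)
#' @param specs named list: method name -> \code{\link{perturbation_spec}}
#' @return an \code{\link{assignment_set}} with one perturbed assignment per
#'   method, deterministic per (seed, method name)
#' @export
generate_method_set <- function(truth, specs) {
  if (!length(specs)) stop("empty perturbation spec map")
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    stop("specs must be a named list (method name -> spec)")
  assignment_set(lapply(names(specs), function(m)
    perturb(truth, specs[[m]], m)))
}

#' Generate a secondary-structure annotation of a given structure class
#'
#' Builds a code string whose helix/strand composition classifies as the
#' requested class under \code{\link{classify_structure}} (round-trip
#' property): all-alpha chains get only helix elements, all-beta only
#' strands, alpha-beta a balanced mix, irregular no elements at all.
#'
#' @param length chain length (>= 10)
#' @param cls target class: all_alpha, all_beta, alpha_beta or irregular
#' @param seed integer seed
#' @return an \code{\link{ss_annotation}} of \code{length} residues
#' @export
generate_ss <- function(length, cls = c("all_alpha", "all_beta",
                                        "alpha_beta", "irregular"),
                        seed = 0L) {
  cls <- match.arg(cls)
  length <- as.integer(length)
  if (length < 10L) stop("length must be >= 10")
  fill_region <- function(out, a, b, code) {
    pos <- a
    while (pos + 3L <= b) {
      run <- sample(4:10, 1L)
      gap <- sample(2:5, 1L)
      end <- min(pos + run - 1L, b)
      out[pos:end] <- code
      pos <- end + gap + 1L
    }
    out
  }
  codes <- with_seed(seed, {
    out <- rep("-", length)
    half <- length %/% 2L
    switch(cls,
           all_alpha = fill_region(out, 1L, length, "H"),
           all_beta = fill_region(out, 1L, length, "E"),
           alpha_beta = fill_region(fill_region(out, 1L, half, "H"),
                                    half + 1L, length, "E"),
           irregular = out)
  })
  ss_annotation(codes)
}
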