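# quick chain-assignment builder: spans is a list of domains, each a list of
# c(start, end) fragments (or a single c(start, end))
ca <- function(spans, method = "m", pdb = "1abc", chain = "A",
               extent = NULL) {
  doms <- lapply(seq_along(spans), function(i) {
    frs <- spans[[i]]
    if (!is.list(frs)) frs <- list(frs)
    domain(sprintf("D%02d", i),
           lapply(frs, function(f) segment(f[1], f[2])))
  })
  suppressWarnings(
    chain_assignment(pdb, chain, method, doms,
                     chain_extent = if (is.null(extent)) NULL
                                    else segment(extent[1], extent[2])))
}

# equal tiling of 1..len into n contiguous domains (distinct partitions for
# distinct n, so sets built from different n never agree)
tiling <- function(n, len = 300, method = paste0("m", n), extent = c(1, len)) {
  cuts <- round(seq(0, len, length.out = n + 1))
  ca(lapply(seq_len(n), function(i) c(cuts[i] + 1, cuts[i + 1])),
     method = method, extent = extent)
}

# seven-method set where the first k methods share one partition and the
# remaining 7-k are mutually disagreeing (distinct domain counts)
seven_method_set <- function(k, len = 420) {
  methods <- consensus_params()$method_order
  shared <- tiling(2, len)
  assigns <- lapply(seq_along(methods), function(i) {
    a <- if (i <= k) shared else tiling(i + 1, len)  # counts 3..8, all distinct
    a$method <- methods[i]
    a
  })
  assignment_set(assigns)
}

# seven-method set with prescribed group sizes, built from partitions with
# distinct domain counts so different groups can never agree
sized_group_set <- function(sizes, len = 420) {
  methods <- consensus_params()$method_order
  stopifnot(sum(sizes) == length(methods))
  assigns <- list()
  i <- 0L
  for (g in seq_along(sizes)) {
    part <- tiling(g + 1, len)   # counts 2, 3, 4, ... per group
    for (k in seq_len(sizes[g])) {
      i <- i + 1L
      part$method <- methods[i]
      assigns[[i]] <- part
    }
  }
  assignment_set(assigns)
}

# independent brute-force agreement oracle: works on raw span lists, not on
# the package's match/canonical machinery
oracle_agree <- function(A, B, thr = 0.8) {
  doms_of <- function(a) {
    doms <- lapply(a$domains, function(d)
      lapply(d$fragments, function(s) s$start:s$end))
    starts <- vapply(doms, function(fr) min(unlist(fr)), numeric(1))
    doms <- doms[order(starts)]
    lapply(doms, function(fr)
      fr[order(vapply(fr, min, numeric(1)))])
  }
  da <- doms_of(A); db <- doms_of(B)
  if (length(da) != length(db)) return(FALSE)
  for (i in seq_along(da)) {
    if (length(da[[i]]) != length(db[[i]])) return(FALSE)
    ra <- unlist(da[[i]]); rb <- unlist(db[[i]])
    ov <- length(intersect(ra, rb))
    if (ov / length(ra) < thr || ov / length(rb) < thr) return(FALSE)
    for (f in seq_along(da[[i]])) {
      fa <- da[[i]][[f]]; fb <- db[[i]][[f]]
      ovf <- length(intersect(fa, fb))
      if (ovf / length(fa) < thr || ovf / length(fb) < thr) return(FALSE)
    }
  }
  TRUE
}

# random valid assignment on a fixed extent, for property tests
random_assignment <- function(seed, len = 200, method = "r") {
  set.seed(seed)
  n <- sample(1:4, 1)
  truth <- generate_true_partition(len, n, seed = seed, method = method)
  spec <- perturbation_spec(boundary_jitter = sample(0:10, 1),
                            merge_prob = runif(1, 0, 0.3),
                            split_prob = runif(1, 0, 0.3),
                            fragment_prob = runif(1, 0, 0.3),
                            seed = seed)
  perturb(truth, spec, method)
}
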