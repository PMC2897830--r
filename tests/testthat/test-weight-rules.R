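# assignment set with a prescribed domain count per method; optionally a
# fragmented first domain for chosen methods
counted_set <- function(counts, fragmented = character(0), len = 600) {
  assigns <- lapply(names(counts), function(m) {
    a <- tiling(counts[[m]], len, method = m)
    if (m %in% fragmented) {
      d1 <- a$domains[[1]]
      s <- d1$fragments[[1]]
      mid <- (s$start + s$end) %/% 2L
      a$domains[[1]] <- domain(d1$domain_id,
                               list(segment(s$start, mid - 3L),
                                    segment(mid + 3L, s$end)))
    }
    a
  })
  assignment_set(assigns)
}

base7 <- c(PDP = 84.4, NCBI = 81.9, DomainParser2 = 78.1, DDomain = 76.5,
           PUU = 74.0, DHcL = 68.3, Dodis = 40.0)
p <- consensus_params()

wrules <- function(S, cls = "irregular") {
  apply_weight_rules(S, cls, group_methods(S, p), p)
}

test_that("no firing condition leaves the base weights untouched", {
  S <- counted_set(list(PDP = 2, NCBI = 2, DomainParser2 = 2, DDomain = 2,
                        PUU = 2, DHcL = 2, Dodis = 2))
  w <- wrules(S)
  expect_equal(w$weights[names(base7)], base7, ignore_attr = TRUE)
  expect_true(all(lengths(w$provenance) == 0))
})

test_that("each count-based rule fires alone on its fixture", {
  # R1: PDP and NCBI both >= 4 domains -> DomainParser2 x 0.9
  S <- counted_set(list(PDP = 4, NCBI = 4, DomainParser2 = 2, DDomain = 2,
                        PUU = 2, DHcL = 2, Dodis = 2))
  w <- wrules(S)
  expect_equal(w$weights[["DomainParser2"]], 78.1 * 0.9)
  expect_equal(w$provenance$DomainParser2, "R1")
  expect_equal(sum(lengths(w$provenance)), 1)

  # R2: PUU predicts more domains than both PDP and NCBI -> PUU x 0.9
  S <- counted_set(list(PDP = 2, NCBI = 2, DomainParser2 = 2, DDomain = 2,
                        PUU = 3, DHcL = 2, Dodis = 2))
  w <- wrules(S)
  expect_equal(w$weights[["PUU"]], 74.0 * 0.9)
  expect_equal(sum(lengths(w$provenance)), 1)

  # R3: PDP >= 5 domains -> NCBI x 0.9 (R1 also needs NCBI >= 4, avoided)
  S <- counted_set(list(PDP = 5, NCBI = 3, DomainParser2 = 2, DDomain = 2,
                        PUU = 2, DHcL = 2, Dodis = 2))
  w <- wrules(S)
  expect_equal(w$weights[["NCBI"]], 73.71)
  expect_equal(w$provenance$NCBI, "R3")
})

test_that("fragmentation rules fire on the methods the conditions name", {
  # R4: three methods fragment -> the non-fragmenting ones are reduced;
  # R5 fires too (PDP and NCBI unfragmented) and reduces the fragmenting ones
  S <- counted_set(list(PDP = 2, NCBI = 2, DomainParser2 = 2, DDomain = 2,
                        PUU = 2, DHcL = 2, Dodis = 2),
                   fragmented = c("PUU", "DDomain", "DHcL"))
  w <- wrules(S)
  expect_equal(w$provenance$PDP, "R4")
  expect_equal(w$provenance$PUU, "R5")
  expect_equal(w$weights[["PDP"]], 84.4 * 0.9)
  expect_equal(w$weights[["PUU"]], 74.0 * 0.9)
  expect_equal(w$weights[["Dodis"]], 40.0 * 0.9)

  # R5 alone: one method fragments, PDP and NCBI do not
  S <- counted_set(list(PDP = 2, NCBI = 2, DomainParser2 = 2, DDomain = 2,
                        PUU = 2, DHcL = 2, Dodis = 2), fragmented = "PUU")
  w <- wrules(S)
  expect_equal(w$provenance$PUU, "R5")
  expect_equal(sum(lengths(w$provenance)), 1)

  # R4 alone: PDP fragments too, so R5's condition fails
  S <- counted_set(list(PDP = 2, NCBI = 2, DomainParser2 = 2, DDomain = 2,
                        PUU = 2, DHcL = 2, Dodis = 2),
                   fragmented = c("PDP", "PUU", "DDomain"))
  w <- wrules(S)
  expect_equal(w$provenance$NCBI, "R4")
  expect_null(w$provenance$PDP)
})

test_that("structure-class rules adjust PDP/NCBI as Table-style conditions state", {
  differ <- list(PDP = 2, NCBI = 3, DomainParser2 = 2, DDomain = 2,
                 PUU = 2, DHcL = 2, Dodis = 2)
  agree <- list(PDP = 2, NCBI = 2, DomainParser2 = 2, DDomain = 2,
                PUU = 2, DHcL = 2, Dodis = 2)
  # R6: all-alpha, counts differ -> PDP x 1.1
  w <- wrules(counted_set(differ), "all_alpha")
  expect_equal(w$weights[["PDP"]], 84.4 * 1.1)
  expect_equal(w$provenance$PDP, "R6")
  # R7: all-beta, counts differ -> PDP x 1.1
  w <- wrules(counted_set(differ), "all_beta")
  expect_equal(w$provenance$PDP, "R7")
  # R8: all-beta, counts equal -> PDP and NCBI x 1.1
  w <- wrules(counted_set(agree), "all_beta")
  expect_equal(w$weights[["PDP"]], 84.4 * 1.1)
  expect_equal(w$weights[["NCBI"]], 81.9 * 1.1)
  # R9: alpha-beta, counts equal -> methods outside PDP's group x 0.9;
  # here every method shares PDP's partition, so nothing changes
  w <- wrules(counted_set(agree), "alpha_beta")
  expect_equal(sum(lengths(w$provenance)), 0)
  # now isolate DHcL and Dodis in their own groups
  S <- counted_set(list(PDP = 2, NCBI = 2, DomainParser2 = 2, DDomain = 2,
                        PUU = 2, DHcL = 3, Dodis = 4))
  w <- wrules(S, "alpha_beta")
  expect_equal(w$provenance$DHcL, "R9")
  expect_equal(w$weights[["Dodis"]], 40.0 * 0.9)
  expect_null(w$provenance$PDP)
})

test_that("rules stack multiplicatively in row order", {
  S <- counted_set(list(PDP = 5, NCBI = 4, DomainParser2 = 2, DDomain = 2,
                        PUU = 6, DHcL = 2, Dodis = 2))
  w <- wrules(S, "all_alpha")  # counts differ -> R6 on top of R1/R2/R3
  expect_equal(w$weights[["DomainParser2"]], 78.1 * 0.9)  # R1
  expect_equal(w$weights[["PUU"]], 74.0 * 0.9)            # R2
  expect_equal(w$weights[["NCBI"]], 81.9 * 0.9)           # R3
  expect_equal(w$weights[["PDP"]], 84.4 * 1.1)            # R6
  expect_equal(w$provenance$NCBI, "R3")
})

test_that("rules referencing absent methods are skipped; unknown methods get weight 50", {
  S <- counted_set(list(PDP = 5, DomainParser2 = 2))  # no NCBI: R1/R3 skip
  w <- wrules(S)
  expect_equal(w$weights[["DomainParser2"]], 78.1)
  expect_warning(
    w2 <- apply_weight_rules(
      assignment_set(list(tiling(2, 600, method = "NewMethod"),
                          tiling(2, 600, method = "PDP"))),
      "irregular", list(list(members = c("PDP", "NewMethod"),
                             representative = "PDP")), p),
    "base weight")
  expect_equal(w2$weights[["NewMethod"]], 50)
})

test_that("weighted reliability is the normalized sum of member weights", {
  # PDP, NCBI, DomainParser2 identical; the rest mutually disagreeing with
  # counts chosen so no rule fires; irregular chain skips class rules
  parts <- list(PDP = 2, DomainParser2 = 2, NCBI = 2, PUU = 1, DDomain = 3,
                DHcL = 4, Dodis = 5)
  S <- counted_set(parts)
  ss <- ss_annotation(strrep("-", 600))
  r <- weighted_consensus(S, ss)
  expect_equal(r$groups[[1]]$reliability, 48.569157, tolerance = 1e-6)
  expect_equal(r$status, "consensus")
  # same grouping without Dodis: denominator shrinks to the present methods
  S6 <- assignment_set(S$assignments[setdiff(names(parts), "Dodis")])
  r6 <- weighted_consensus(S6, ss)
  expect_equal(r6$groups[[1]]$reliability, 52.763385, tolerance = 1e-6)
})

test_that("uniform weights with no rule adjustment reproduce simple consensus", {
  pu <- consensus_params(
    base_weights = stats::setNames(rep(50, 7), consensus_params()$method_order),
    rule_adjustment = 0)
  for (s in 1:10) {
    set.seed(s)
    truth <- generate_true_partition(300, sample(1:4, 1), seed = s)
    specs <- stats::setNames(lapply(1:7, function(i)
      perturbation_spec(boundary_jitter = sample(0:20, 1),
                        merge_prob = runif(1), seed = s * 13 + i)),
      pu$method_order)
    S <- generate_method_set(truth, specs)
    ss <- generate_ss(300, sample(c("all_alpha", "all_beta", "alpha_beta"),
                                  1), seed = s)
    rs <- simple_consensus(S, pu)
    rw <- weighted_consensus(S, ss, pu)
    expect_equal(vapply(rw$groups, `[[`, numeric(1), "reliability"),
                 vapply(rs$groups, `[[`, numeric(1), "reliability"),
                 tolerance = 1e-12)
    expect_identical(rw$status, rs$status)
  }
})
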