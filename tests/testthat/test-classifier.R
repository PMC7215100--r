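test_that("the three rules fire in order on representative cases", {
  cfg <- classifier_config()
  # rule 1: same key -> disease-centric, targets never examined (even absent)
  dc <- make_case("NilotinibLike", "C04", "C04")
  expect_equal(classify_case(dc, cfg = cfg)$label, "disease_centric")
  # rule 2: shared identifier across distinct keys -> target-centric
  tc <- make_case("SildenafilLike", "C23", "F03", ot = "PDE5A", st = "PDE5A")
  res <- classify_case(tc, cfg = cfg)
  expect_equal(res$label, "target_centric")
  expect_equal(res$match_type, "identical_id")
  # rule 3: residual -> drug-centric
  dr <- make_case("ValproateLike", "C10", "C16", ot = c("ALDH5A1", "ABAT"),
                  st = "HDAC2")
  expect_equal(classify_case(dr, cfg = cfg)$label, "drug_centric")
})

test_that("rule precedence: equal keys win regardless of targets", {
  case <- make_case("X", "C08", "C08", ot = "AAA", st = "BBB")
  expect_equal(classify_case(case)$label, "disease_centric")
})

test_that("the ortholog branch uses sequences and the strict threshold", {
  withr::with_seed(3, {
    a <- random_protein(200)
    # high-identity partner: mutate 20% of positions
    chars <- strsplit(a, "")[[1]]
    hit <- which(stats::runif(200) < 0.2)
    for (i in hit) chars[i] <- sample(setdiff(AA20_TEST, chars[i]), 1)
    b <- paste(chars, collapse = "")
    # unrelated partner, re-drawn until genuinely below the ortholog line
    # (random pairs sit near the twilight zone under this statistic)
    repeat {
      u <- random_protein(200)
      idu <- identity_fraction(global_align(a, u, align_scoring()))
      if (!ortholog_decision(idu)$is_ortholog) break
    }
  })
  seqs <- c(ORIG1 = a, SEC1 = b, SEC2 = u)
  ortho <- make_case("KetoLike", "C01", "C25", ot = "ORIG1", st = "SEC1")
  res <- classify_case(ortho, sequences = seqs)
  expect_equal(res$label, "target_centric")
  expect_equal(res$match_type, "ortholog")
  expect_gt(res$identity, 0.3)
  # unrelated sequence pair falls through to drug-centric
  far <- make_case("AlloLike", "C04", "C03", ot = "ORIG1", st = "SEC2")
  expect_equal(classify_case(far, sequences = seqs)$label, "drug_centric")
  # without sequences, only identical identifiers can fire rule 2
  expect_equal(classify_case(ortho)$label, "drug_centric")
})

test_that("raising the identity threshold never moves drug- to target-centric", {
  withr::with_seed(8, {
    a <- random_protein(150)
    chars <- strsplit(a, "")[[1]]
    for (i in which(stats::runif(150) < 0.45)) {
      chars[i] <- sample(setdiff(AA20_TEST, chars[i]), 1)
    }
    b <- paste(chars, collapse = "")
  })
  seqs <- c(TA = a, TB = b)
  case <- make_case("Borderline", "C01", "C04", ot = "TA", st = "TB")
  labels <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    classify_case(case, seqs, classifier_config(identity_threshold = th))$label
  }, "")
  # once drug_centric at some threshold, stays drug_centric above it
  is_target <- labels == "target_centric"
  expect_true(all(diff(is_target) <= 0))
})

test_that("target_match_mode all_shared is stricter than any_shared", {
  case <- make_case("Chlorpromazine-like", "C23", "F03",
                    ot = c("DRD2", "HTR2A"), st = c("HTR2A", "NEW1"))
  expect_equal(
    classify_case(case, cfg = classifier_config())$label, "target_centric")
  expect_equal(
    classify_case(case,
                  cfg = classifier_config(target_match_mode = "all_shared")
    )$label, "drug_centric")
})

test_that("rule 2 with both target sets empty is a classification error", {
  case <- make_case("NoTargets", "C04", "C10")
  expect_error(classify_case(case), "NoTargets")
  expect_error(classify_all(case), "classification failed")
})

test_that("classify_all equals element-wise classify_case and partitions", {
  corp <- rdd_corpus()
  cl <- classify_all(corp$cases, corp$sequences)
  expect_equal(cl$n_disease + cl$n_target + cl$n_drug, cl$n_total)
  expect_true(all(cl$per_case$label %in%
                    c("disease_centric", "target_centric", "drug_centric")))
  # element-wise recomputation oracle on a sample of cases
  idx <- seq(1, 128, by = 7)
  for (i in idx) {
    one <- classify_case(corp$cases[i, , drop = FALSE], corp$sequences)
    expect_equal(one$label, cl$per_case$label[i], info = i)
  }
})

test_that("percentages are rounded half-up and empty corpora are flagged", {
  cl <- classify_all(bind_cases(make_case("A", "C04", "C04"),
                                make_case("B", "C04", "C04"),
                                make_case("C", "C04", "C10",
                                          ot = "T1", st = "T1")))
  expect_equal(cl$pct_disease, 67)  # 2/3 -> 66.67 -> 67
  expect_equal(cl$pct_target, 33)
  empty <- classify_all(repo_cases(character(), character(), character(),
                                   character(), character(), character()))
  expect_true(empty$empty)
  expect_equal(empty$pct_disease, 0L)
})

test_that("count_ortholog_cases separates ortholog from identical-id matches", {
  corp <- rdd_corpus()
  cl <- classify_all(corp$cases, corp$sequences)
  expect_equal(count_ortholog_cases(cl), 5L)
  # corpus with only identical-ID matches -> 0
  cl2 <- classify_all(bind_cases(
    make_case("A", "C04", "C10", ot = "T1", st = "T1"),
    make_case("B", "C01", "C25", ot = "T2", st = "T2")))
  expect_equal(count_ortholog_cases(cl2), 0L)
})

test_that("planted labels are recovered exactly on synthetic corpora", {
  cfg <- generator_config(n_cases = 40, seq_length = 250, mutation_rate = 0.2,
                          seed = 21)
  sim <- generate_cases(cfg)
  cl <- classify_all(sim$cases, sim$sequences)
  expect_identical(cl$per_case$label, sim$labels$planted_label)
  # planted ortholog cases are exactly the ones classified via orthology
  expect_equal(count_ortholog_cases(cl), sum(sim$labels$ortholog))
})
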