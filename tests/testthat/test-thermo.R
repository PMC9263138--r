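test_that("pair states classify the stem walk correctly", {
  tr <- validate_target("GCGC")
  st_wt <- pair_states(design_wt(tr))
  expect_true(all(st_wt$state == "WC"))
  st_gu <- pair_states(design_gu(tr))
  expect_equal(st_gu$state, c("WC", "GU", "WC", "GU"))
  expect_equal(st_gu$sense_base, c("G", "U", "G", "U"))
  withr::with_seed(51, {
    for (rep in 1:5) {
      d <- design_hairpin(validate_target(random_dna(90)),
                          sample(c("wt", "gu", "m1in4", "m2in10"), 1))
      expect_equal(pair_states(d)$state, brute_pair_walk(d))
    }
  })
})

test_that("mismatch designs show exactly block mismatches per complete window", {
  tr <- random_target(200, 50, seed = 17)
  st <- pair_states(design_mismatch(tr, 4, 1))
  mm <- which(st$state == "MISMATCH")
  expect_equal(length(mm), 50L)
  for (w in seq_len(50)) {
    expect_equal(sum(mm > (w - 1) * 4 & mm <= w * 4), 1L)
  }
})

test_that("the bundled parameter set loads, checks its checksum, and is named", {
  p <- duplex_params("turner2004")
  expect_equal(p$id, "turner2004")
  expect_length(p$stacks, 36L)
  # canonical literature values survive the bundling
  expect_equal(unname(p$stacks[["GC/GC"]]), -3.40)
  expect_equal(unname(p$stacks[["CG/CG"]]), -2.40)
  expect_equal(unname(p$stacks[["AU/UA"]]), -0.90)
  expect_error(duplex_params("turner1999"), class = "hairpinr_parameter_error")
})

test_that("free energy is deterministic and requires >= 2 positions", {
  tr <- random_target(100, 25, seed = 19)
  d <- design_gu(tr)
  expect_identical(duplex_free_energy(pair_states(d)),
                   duplex_free_energy(pair_states(d)))
  one <- pair_states(design_wt(validate_target("AT")))[1, ]
  expect_error(duplex_free_energy(one), class = "hairpinr_parameter_error")
})

test_that("every WC->GU stack replacement in the table is destabilizing", {
  p <- duplex_params()
  neighbours <- c("CG", "GC", "GU", "UG", "AU", "UA")
  # a sense C -> U change turns a C:G pair (type CG) into U:G (type UG) and a
  # paired G:C (type GC as seen from the partner stack) into G:U
  for (nb in neighbours) {
    expect_gt(p$stacks[[paste0(nb, "/UG")]], p$stacks[[paste0(nb, "/CG")]])
    expect_gt(p$stacks[[paste0("UG/", nb)]], p$stacks[[paste0("CG/", nb)]])
    expect_gt(p$stacks[[paste0(nb, "/GU")]], p$stacks[[paste0(nb, "/GC")]])
    expect_gt(p$stacks[[paste0("GU/", nb)]], p$stacks[[paste0("GC/", nb)]])
  }
})

test_that("WT is strictly more stable than G:U whenever the target has a C", {
  withr::with_seed(61, {
    for (rep in 1:10) {
      tr <- validate_target(random_dna(60))
      if (!grepl("C", tr$sequence)) next
      dg_wt <- duplex_free_energy(pair_states(design_wt(tr)))
      dg_gu <- duplex_free_energy(pair_states(design_gu(tr)))
      expect_lt(dg_wt, dg_gu)
    }
  })
})

test_that("single-position perturbation to GU or mismatch never stabilizes", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      tr <- validate_target(random_dna(30))
      st <- pair_states(design_wt(tr))
      dg0 <- duplex_free_energy(st)
      for (i in seq_len(nrow(st))) {
        # mismatch: sense base set to self-pair with the antisense base
        st_mm <- st
        st_mm$sense_base[i] <- st_mm$antisense_base[i]
        st_mm$state[i] <- "MISMATCH"
        expect_gte(duplex_free_energy(st_mm), dg0)
        # the wobble the designs create: sense C -> U turns C:G into U:G
        pr <- paste0(st$sense_base[i], st$antisense_base[i])
        if (pr == "CG") {
          st_gu <- st
          st_gu$sense_base[i] <- "U"
          st_gu$state[i] <- "GU"
          expect_gte(duplex_free_energy(st_gu), dg0)
        }
      }
    }
  })
})

test_that("the stacking scan is additive over a split stem", {
  p <- duplex_params()
  withr::with_seed(81, {
    for (rep in 1:5) {
      tr <- validate_target(random_dna(40))
      st <- pair_states(design_wt(tr))
      k <- sample(5:35, 1)
      left <- st[1:k, ]
      right <- st[(k + 1):nrow(st), ]
      junction <- p$stacks[[paste0(
        st$sense_base[k], st$antisense_base[k], "/",
        st$antisense_base[k + 1], st$sense_base[k + 1]
      )]]
      expect_equal(
        hairpinr:::stack_sum(st, p),
        hairpinr:::stack_sum(left, p) + hairpinr:::stack_sum(right, p) +
          junction
      )
    }
  })
})

test_that("pure-WC duplex energies agree with an independent folding oracle", {
  skip_if(!rnaduplex_available(), "RNAduplex oracle not on PATH")
  withr::with_seed(91, {
    for (len in c(6, 10, 15, 20)) {
      tr <- validate_target(random_dna(len))
      d <- design_wt(tr)
      mine <- duplex_free_energy(pair_states(d))
      oracle <- rnaduplex_energy(d$sense_arm, d$antisense_arm)
      expect_lt(abs(mine - oracle), max(0.1 * abs(oracle), 0.25))
    }
  })
})

test_that("scheme ranking reproduces the qualitative stability order", {
  withr::with_seed(101, {
    wt_first <- m1in4_last <- 0L
    n <- 20L
    for (rep in seq_len(n)) {
      tr <- random_target(200, sample(40:60, 1), seed = 1000 + rep)
      ranked <- score_schemes(tr)
      if (ranked$scheme[1] == "wt") wt_first <- wt_first + 1L
      if (ranked$scheme[4] == "m1in4") m1in4_last <- m1in4_last + 1L
    }
    expect_equal(wt_first, n)
    expect_gte(m1in4_last / n, 0.9)
  })
})

test_that("rank_designs breaks ties deterministically and rejects mixed targets", {
  tr <- random_target(50, 12, seed = 23)
  r1 <- duplex_report(design_wt(tr))
  expect_equal(nrow(rank_designs(list(r1))), 1L)
  tr2 <- random_target(50, 12, seed = 24, id = "other_target")
  r2 <- duplex_report(design_wt(tr2))
  expect_error(rank_designs(list(r1, r2)),
               class = "hairpinr_mixed_target_error")
  # identical energies fall back to design_id order
  ranked <- rank_designs(list(r1, r1))
  expect_equal(ranked$delta_g[1], ranked$delta_g[2])
  expect_equal(ranked$design_id, sort(ranked$design_id))
})

test_that("duplex report counts partition the stem", {
  tr <- random_target(200, 52, seed = 29)
  for (scheme in c("wt", "gu", "m1in4", "m2in10")) {
    rep_ <- duplex_report(design_hairpin(tr, scheme))
    expect_equal(rep_$n_wc + rep_$n_gu + rep_$n_mm, 200L)
    if (scheme == "wt") expect_equal(rep_$n_gu + rep_$n_mm, 0L)
  }
})
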