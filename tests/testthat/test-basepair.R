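template_residue <- function(base, chain = "A", seqid = 1L,
                             transform = diag(3), shift = c(0, 0, 0)) {
  t <- base_templates()[[base]]
  t <- t[t$atom != "P", ]
  xyz <- as.matrix(t[, c("x", "y", "z")]) %*% t(transform)
  data.frame(name = t$atom, element = substr(t$atom, 1, 1),
             x = xyz[, 1] + shift[1], y = xyz[, 2] + shift[2],
             z = xyz[, 3] + shift[3],
             occupancy = 1, altloc = "", bfactor = 0,
             resname = paste0("D", base), seqid = seqid, icode = "",
             chain = chain, is_hetatm = FALSE, stringsAsFactors = FALSE)
}

test_that("base_frame recovers constructed frames exactly", {
  # template in standard position
  f <- base_frame(template_residue("A"))
  expect_equal(f$frame, diag(3), tolerance = 1e-9)
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  # known rotation and translation
  set.seed(8)
  for (base in c("A", "T", "G", "C")) {
    R <- minorgroove:::random_rotation(); tr <- rnorm(3, sd = 10)
    f <- base_frame(template_residue(base, transform = R, shift = tr))
    expect_equal(f$frame, R, tolerance = 1e-9)
    expect_equal(f$origin, tr, tolerance = 1e-9)
    expect_lt(f$rmsd, 1e-9)
  }
})

test_that("fit rmsd is invariant under global rigid motion", {
  s <- perturb_coordinates(build_duplex("GATC", preset_profile("ideal_b", 4)),
                           0.05, 21)
  res <- minorgroove:::split_residues(s)
  set.seed(9)
  R <- minorgroove:::random_rotation(); tr <- rnorm(3, sd = 30)
  sm <- minorgroove:::transform_structure(s, R, tr)
  resm <- minorgroove:::split_residues(sm)
  for (k in seq_along(res))
    expect_equal(base_frame(res[[k]])$rmsd, base_frame(resm[[k]])$rmsd,
                 tolerance = 1e-6)
})

test_that("base_frame rejects unusable residues", {
  r <- template_residue("A")
  expect_error(base_frame(r[r$name %in% c("N9", "C8", "N7", "C1'"), ]),
               "need >= 6")
  bad <- r; bad$resname <- "ALA"
  expect_error(base_frame(bad), "not a canonical deoxynucleotide")
})

test_that("find_base_pairs recovers the builder register", {
  s <- build_duplex("TATATATATATATATA", preset_profile("ideal_b", 16))
  pairs <- find_base_pairs(s)
  expect_s3_class(pairs, "basepair_list")
  expect_length(pairs, 16L)
  for (k in seq_along(pairs)) {
    expect_equal(pairs[[k]]$frameI$chain, "A")
    expect_equal(pairs[[k]]$frameI$seqid, k)
    expect_equal(pairs[[k]]$frameII$seqid, 17L - k)
  }
})

test_that("pair search matches a brute-force enumeration", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    s <- build_duplex(random_sequence(n), random_profile(n))
    pairs <- find_base_pairs(s)
    expect_length(pairs, n)
    # brute force: every residue pair in both orders under the same criteria
    res <- minorgroove:::split_residues(s)
    res <- Filter(function(r) r$resname[1] %in% c("DA", "DT", "DG", "DC"), res)
    frames <- lapply(res, base_frame)
    hits <- list()
    for (i in seq_along(res)) for (j in seq_along(res)) {
      if (i == j) next
      h <- minorgroove:::pair_candidate(res[[i]], res[[j]],
                                        frames[[i]], frames[[j]])
      if (!is.null(h))
        hits[[length(hits) + 1L]] <-
          paste(sort(c(minorgroove:::residue_key(res[[i]]),
                       minorgroove:::residue_key(res[[j]]))), collapse = "|")
    }
    # symmetry: every hit appears exactly twice (i,j) and (j,i)
    expect_true(all(table(unlist(hits)) == 2L))
    got <- sort(vapply(pairs, function(p)
      paste(sort(c(minorgroove:::residue_key(p$resI),
                   minorgroove:::residue_key(p$resII))), collapse = "|"),
      character(1)))
    expect_identical(got, sort(unique(unlist(hits))))
  }
})

test_that("no-pair inputs warn rather than error", {
  prot <- new_structure(stub_protein_atoms(matrix(rnorm(9), 3)), "prot")
  pairs <- find_base_pairs(prot)
  expect_length(pairs, 0L)
  expect_match(attr(pairs, "warnings"), "fewer than two", all = FALSE)
})

test_that("intra parameters: identity pair and constructed propeller", {
  s0 <- build_duplex("AT", preset_profile("ideal_b", 2))
  p <- find_base_pairs(s0)[[1]]
  expect_equal(unname(intra_bp_params(p)), rep(0, 6), tolerance = 1e-6)
  # strand-II base pre-rotated about the pairing long axis -> propeller
  prof <- preset_profile("ideal_b", 4)
  prof$intra$propeller <- -11.2
  s <- build_duplex("TTTT", prof)
  got <- basepair_tables(find_base_pairs(s))$intra$propeller
  expect_equal(got, rep(-11.2, 4), tolerance = 0.1)
})

test_that("step parameters: canonical B step and builder round trip", {
  f1 <- diag(3); o1 <- c(0, 0, 0)
  f2 <- minorgroove:::rot_z(36 * pi / 180); o2 <- c(0, 0, 3.4)
  dec <- minorgroove:::step_decompose(f1, o1, f2, o2)
  expect_equal(unname(dec$par), c(0, 0, 3.4, 0, 0, 36), tolerance = 1e-9)
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    prof <- random_profile(n)
    s <- build_duplex(random_sequence(n), prof)
    tabs <- basepair_tables(find_base_pairs(s))
    expect_equal(as.matrix(tabs$intra[, c("buckle", "propeller", "opening")]),
                 as.matrix(prof$intra[, c("buckle", "propeller", "opening")]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(as.matrix(tabs$step[, c("shift", "slide", "rise",
                                         "tilt", "roll", "twist")]),
                 as.matrix(prof$step), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("h_twist equals the screw-axis rotation angle", {
  s <- build_duplex("ATAT", preset_profile("ideal_b", 4))
  tabs <- basepair_tables(find_base_pairs(s))
  # pure twist: both conventions coincide
  expect_equal(tabs$step$h_twist, tabs$step$twist, tolerance = 1e-6)
  # with roll, compare against the rotation angle of the composed step matrix
  prof <- preset_profile("ideal_b", 4); prof$step$roll <- 10
  tabs2 <- basepair_tables(find_base_pairs(build_duplex("ATAT", prof)))
  R <- minorgroove:::rot_z(18 * pi / 180) %*%
    minorgroove:::rot_y(10 * pi / 180) %*% minorgroove:::rot_z(18 * pi / 180)
  ang <- acos((sum(diag(R)) - 1) / 2) * 180 / pi
  expect_equal(tabs2$step$h_twist, rep(ang, 3), tolerance = 1e-6)
})

test_that("swapping the reference strand applies the standard sign flips", {
  set.seed(23)
  n <- 7
  s <- build_duplex(random_sequence(n), random_profile(n))
  tA <- basepair_tables(find_base_pairs(s, ref_chain = "A"))
  tB <- basepair_tables(find_base_pairs(s, ref_chain = "B"))
  ri <- tB$intra[rev(seq_len(n)), ]
  for (cl in c("shear", "buckle"))
    expect_equal(ri[[cl]], -tA$intra[[cl]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  for (cl in c("stretch", "stagger", "propeller", "opening"))
    expect_equal(ri[[cl]], tA$intra[[cl]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  rs <- tB$step[rev(seq_len(n - 1)), ]
  for (cl in c("shift", "tilt"))
    expect_equal(rs[[cl]], -tA$step[[cl]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  for (cl in c("slide", "rise", "roll", "twist"))
    expect_equal(rs[[cl]], tA$step[[cl]], tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("average_params filters and summarizes", {
  s <- build_duplex("TATATA", preset_profile("ta_like", 6))
  tabs <- basepair_tables(find_base_pairs(s))
  avg <- average_params(tabs$intra, tabs$step)
  sm <- avg$summary
  expect_equal(sm$mean[sm$parameter == "propeller"], -11.2, tolerance = 1e-6)
  expect_equal(sm$sd[sm$parameter == "propeller"], 0, tolerance = 1e-6)
  expect_equal(sm$n[sm$parameter == "twist"], 5)
  # single pair: mean equals the value, sd 0
  one <- average_params(tabs$intra[1, , drop = FALSE])
  expect_equal(one$summary$mean[one$summary$parameter == "propeller"], -11.2,
               tolerance = 1e-6)
  expect_equal(one$summary$sd, rep(0, 6))
  # hand-computed mean on a mixed profile
  prof <- preset_profile("ideal_b", 4)
  prof$intra$propeller <- c(-4, -8, -12, -16)
  tabs2 <- basepair_tables(find_base_pairs(build_duplex("ATAT", prof)))
  avg2 <- average_params(tabs2$intra, tabs2$step)
  expect_equal(avg2$summary$mean[avg2$summary$parameter == "propeller"], -10,
               tolerance = 1e-6)
  # exclusion bookkeeping
  fake <- tabs$intra; fake$fit_rmsd_I[2] <- 0.9
  avg3 <- average_params(fake, tabs$step)
  expect_equal(avg3$excluded$pairs$i, 2)
  expect_equal(avg3$summary$n[avg3$summary$parameter == "propeller"], 5)
  expect_error(average_params(tabs$intra[0, ]), "no base pairs")
})
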