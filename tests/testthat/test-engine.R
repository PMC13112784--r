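test_that("every satisfying probe yields its label once; violations never do", {
  for (lb in names(default_registry())) {
    det <- detect_interactions(make_probe(lb, satisfy = TRUE))
    expect_equal(sum(vapply(det$hits, `[[`, "", "label") == lb), 1,
                 info = paste("satisfying probe for", lb))
    det0 <- detect_interactions(make_probe(lb, satisfy = FALSE))
    expect_equal(sum(vapply(det0$hits, `[[`, "", "label") == lb), 0,
                 info = paste("violating probe for", lb))
  }
})

test_that("engine agrees with the exhaustive all-pairs oracle on every fixture", {
  systems <- c(lapply(names(default_registry()), make_probe),
               list(make_toy_complex()$system))
  for (sys in systems) {
    det <- detect_interactions(sys)
    expect_equal(engine_hit_keys(det), oracle_hits(sys))
  }
})

test_that("accepted hits satisfy their printed inequalities when re-measured", {
  toy <- make_toy_complex()$system
  det <- detect_interactions(toy)
  for (h in det$hits)
    expect_true(remeasure_hit(toy, h), info = h$label)
  for (lb in direct_labels()) {
    sys <- make_probe(lb)
    for (h in detect_interactions(sys)$hits)
      expect_true(remeasure_hit(sys, h), info = paste(lb, "->", h$label))
  }
})

test_that("priority keeps at most one label per atom pair, vdW last", {
  toy <- make_toy_complex()$system
  det <- detect_interactions(toy)
  pairs <- vapply(det$hits, function(h)
    paste(h$target, paste(h$pair, collapse = "-")), "")
  expect_false(anyDuplicated(pairs) > 0)
  # the CH...O pair is inside the vdW gate but is never labelled vdW
  cho <- Filter(function(h) h$label == "CH_O", det$hits)[[1]]
  expect_false(any(vapply(det$hits, function(h)
    h$label == "vdW" && identical(h$pair, cho$pair), logical(1))))
})

test_that("spatial culling is lossless", {
  toy <- make_toy_complex()$system
  expect_equal(engine_hit_keys(detect_interactions(toy, cull = 8)),
               engine_hit_keys(detect_interactions(toy, cull = Inf)))
})

test_that("hit decisions are invariant under rigid motion", {
  toy <- make_toy_complex()
  rot <- random_rotation(17)
  moved <- transform_system(toy$system, rot, c(12, -7, 3))
  d1 <- detect_interactions(toy$system)
  d2 <- detect_interactions(moved)
  expect_equal(engine_hit_keys(d1), engine_hit_keys(d2))
  expect_equal(aggregate_descriptors(d2$hits, d2$bridges, "grouped"),
               toy$expected_grouped)
})

test_that("buffer monotonicity: larger buffers only add distance-gated hits", {
  toy <- make_toy_complex()$system
  labelled_pairs <- function(buffer) {
    p <- default_rule_params(); p$vdw_buffer <- buffer
    det <- detect_interactions(toy, params = p)
    vapply(det$hits, function(h)
      paste(h$target, paste(h$pair, collapse = "-")), "")
  }
  p08 <- labelled_pairs(0.8); p10 <- labelled_pairs(1.0)
  p12 <- labelled_pairs(1.2)
  expect_true(all(p08 %in% p10))
  expect_true(all(p10 %in% p12))
  # each satisfying probe keeps its label as the buffer grows
  for (lb in c("CH_O", "CH_PI", "vdW", "S_O", "HB_NH_O")) {
    p <- default_rule_params(); p$vdw_buffer <- 1.2
    det <- detect_interactions(make_probe(lb), params = p)
    expect_gte(sum(vapply(det$hits, `[[`, "", "label") == lb), 1)
  }
})

test_that("two target residues produce deduplicated M-M hits", {
  toy <- make_toy_complex()$system
  dpm <- assign_partner_classes(toy, list(
    targets = list("H:57", "A:10"),
    chains = c(H = "Ab", A = "Ab", B = "Ag")))
  det <- detect_interactions(dpm)
  mm <- Filter(function(h) h$partner_class == "M", det$hits)
  expect_gte(length(mm), 1)
  keys <- vapply(mm, function(h)
    paste(paste(sort(c(h$target, h$partner)), collapse = "|"),
          paste(h$pair, collapse = "-")), "")
  expect_false(anyDuplicated(keys) > 0)
  # the former M -> Ab CH...O contact is now an inter-mutant M hit
  expect_true(any(vapply(mm, function(h) h$label == "CH_O", logical(1))))
})

test_that("water bridges require both legs; lone-M waters yield none", {
  toy <- make_toy_complex()
  det <- detect_interactions(toy$system)
  expect_length(det$bridges, 1)
  b <- det$bridges[[1]]
  expect_equal(b$leg1$target, "H:57")
  expect_equal(b$leg1$partner, b$water)
  expect_equal(b$leg2$partner_class, "Ag")
  expect_equal(descriptor_name(b), "M#HB_NH_O#S#HB_OH_O#Ag")
  # W:302 touches only the target: contributes M-S but never a bridge
  expect_false(any(vapply(det$bridges, `[[`, "", "water") == "W:302"))
  expect_true(any(vapply(det$hits, function(h)
    h$partner == "W:302", logical(1))))

  # deleting the waters zeroes the water terms, direct hits unchanged
  at <- toy$system$atoms
  dry <- mol_system(at[!at$is_water, setdiff(names(at), c("reskey", "is_water"))],
                    toy$system$bonds[toy$system$bonds$a %in%
                                       at$serial[!at$is_water] &
                                     toy$system$bonds$b %in%
                                       at$serial[!at$is_water], ])
  dry <- assign_partner_classes(dry, list(targets = list("H:57"),
                                          chains = c(H = "Ab", A = "Ab",
                                                     B = "Ag")))
  ddet <- detect_interactions(dry)
  g <- aggregate_descriptors(ddet$hits, ddet$bridges, "grouped")
  expect_equal(unname(g["M##S"]), 0L)
  expect_equal(unname(g["M##S##"]), 0L)
  direct <- setdiff(names(g), c("M##S", "M##S##"))
  expect_equal(g[direct], toy$expected_grouped[direct])
})

test_that("hit files are deterministic; empty runs are header-only", {
  toy <- make_toy_complex()$system
  det <- detect_interactions(toy)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hits(det$hits, det$bridges, toy, f1)
  write_hits(det$hits, det$bridges, toy, f2)
  expect_identical(readLines(f1), readLines(f2))
  l <- readLines(f1)
  expect_match(l[1], "^descriptor\t")
  expect_length(l, 1 + length(det$hits) + length(det$bridges))
  expect_true(any(startsWith(l, "M#CH_O#Ab\t")))
  f0 <- withr::local_tempfile()
  write_hits(list(), list(), toy, f0)
  expect_length(readLines(f0), 1)
})

test_that("PyMOL scripts color families correctly and omit vdW", {
  toy <- make_toy_complex()$system
  det <- detect_interactions(toy)
  f <- withr::local_tempfile(fileext = ".pml")
  write_pml(det$hits, det$bridges, f)
  l <- readLines(f)
  expect_true(any(grepl("^color blue, .*HB_NH_O", l)))
  expect_true(any(grepl("^color cyan, .*Ele_NH_O", l)))
  expect_true(any(grepl("^color orange, .*CH_PI", l)))
  expect_true(any(grepl("^color pink, .*CH_O", l)))
  expect_false(any(grepl("vdW", l)))
  # a vdW-only hit set draws nothing
  det_v <- detect_interactions(make_probe("vdW"))
  fv <- withr::local_tempfile(fileext = ".pml")
  write_pml(det_v$hits, det_v$bridges, fv)
  expect_false(any(grepl("^distance", readLines(fv))))
  # the orthogonal multipolar convention is yellow
  det_o <- detect_interactions(make_probe("OMulPol"))
  fo <- withr::local_tempfile(fileext = ".pml")
  write_pml(det_o$hits, det_o$bridges, fo)
  expect_true(any(grepl("^color yellow, .*OMulPol", readLines(fo))))
})
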