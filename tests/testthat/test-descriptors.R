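fake_hit <- function(label, partner_class, target = "H:57",
                     partner = "A:1", pair = c(1, 2))
  list(label = label, target = target, partner = partner,
       partner_class = partner_class, pair = pair,
       roles = c(A1 = pair[1], A2 = pair[2]), measured = list(d = 3.0))

fake_bridge <- function(l1, l2, cls = "Ab")
  list(water = "W:1",
       leg1 = fake_hit(l1, "S", partner = "W:1"),
       leg2 = list(label = l2, target = NA, partner = "A:2",
                   partner_class = cls, pair = c(3, 4),
                   roles = c(A1 = 3, A2 = 4), measured = list(d = 3.0)))

test_that("descriptor names encode label and partner class", {
  expect_equal(descriptor_name(fake_hit("CH_O", "Ag")), "M#CH_O#Ag")
  expect_equal(descriptor_name(fake_hit("vdW", "M")), "M#vdW#M")
  expect_equal(descriptor_name(fake_hit("HB_OH_O", "S")), "M#HB_OH_O#S")
  expect_equal(descriptor_name(fake_bridge("HB_OH_O", "HB_NH_O")),
               "M#HB_OH_O#S#HB_NH_O#Ab")
  expect_error(descriptor_name(fake_hit("CH_O", "??")), "partner class")
})

test_that("grouped aggregation erases partners and pools water terms", {
  hits <- list(fake_hit("CH_O", "Ab"), fake_hit("CH_O", "Ag"),
               fake_hit("HB_NH_O", "S"), fake_hit("Fe_A", "Ag"))
  bridges <- list(fake_bridge("HB_OH_O", "HB_OH_O"))
  g <- aggregate_descriptors(hits, bridges, "grouped")
  expect_length(g, 30)
  expect_equal(unname(g["M#CH_O#"]), 2L)       # partner identity erased
  expect_equal(unname(g["M##S"]), 1L)
  expect_equal(unname(g["M##S##"]), 1L)
  expect_false("M#Fe_A#" %in% names(g))         # metals excluded
  expect_equal(sum(g), 4L)
  # empty inputs give the all-zero 30-vector
  g0 <- aggregate_descriptors(list(), list(), "grouped")
  expect_length(g0, 30)
  expect_true(all(g0 == 0L))
})

test_that("count conservation holds on the toy complex", {
  toy <- make_toy_complex()
  det <- detect_interactions(toy$system)
  g <- aggregate_descriptors(det$hits, det$bridges, "grouped")
  expect_equal(g, toy$expected_grouped)
  direct_keys <- paste0("M#", direct_labels(), "#")
  excl <- setdiff(names(default_registry()), direct_labels())
  kept <- Filter(function(h) !(h$label %in% excl), det$hits)
  expect_equal(sum(g[direct_keys]) + g[["M##S"]], length(kept))
  expect_equal(unname(g["M##S##"]), length(det$bridges))
})

test_that("water-capable satisfiability reproduces the 11/11/55 arithmetic", {
  wc <- water_capable_labels()
  expect_length(wc, 11)
  expect_setequal(wc, c("HB_OH_O", "HB_NH_O", "HB_OH_N", "Ele_OH_O",
                        "Ele_NH_O", "Ele_OH_N", "CH_O", "OH_S", "SH_O",
                        "OH_PI", "vdW"))
  expect_false("CH_PI" %in% wc)   # water has neither C-H nor a pi system
  expect_false("HB_NH_N" %in% wc) # nitrogen needed on both sides
  expect_equal(choose(length(wc), 2), 55)
  keys <- descriptor_keys("individual")
  expect_length(keys, 28 + 11 + 11 + 55)
  expect_equal(sum(grepl("^M#[^#]+#S$", keys)), 11)
  expect_equal(sum(grepl("^M#([^#]+)#S#\\1#$", keys)), 11)
})

test_that("individual mode resolves water contacts and unordered bridges", {
  hits <- list(fake_hit("CH_O", "Ab"), fake_hit("HB_NH_O", "S"))
  bridges <- list(fake_bridge("HB_OH_O", "HB_OH_O"),
                  fake_bridge("HB_NH_O", "HB_OH_O"),
                  fake_bridge("HB_OH_O", "HB_NH_O"))
  v <- aggregate_descriptors(hits, bridges, "individual")
  expect_equal(unname(v["M#CH_O#"]), 1L)
  expect_equal(unname(v["M#HB_NH_O#S"]), 1L)
  expect_equal(unname(v["M#HB_OH_O#S#HB_OH_O#"]), 1L)
  # mixed bridges count as unordered label pairs
  expect_equal(unname(v["M#HB_OH_O#S#HB_NH_O#"]), 2L)
})

test_that("descriptor tables round-trip through CSV", {
  toy <- make_toy_complex()
  det <- detect_interactions(toy$system)
  g <- aggregate_descriptors(det$hits, det$bridges, "grouped")
  f <- withr::local_tempfile(fileext = ".csv")
  meta <- data.frame(structure = "toy", target = "H:57",
                     rotamer_energy = 0.41)
  write_descriptor_table(list(g), f, metadata = meta)
  back <- read_descriptor_table(f)
  expect_equal(ncol(back), 3 + 30)   # metadata + 30 descriptors
  expect_equal(as.integer(back[1, names(g)]), unname(g))
  # 30 interaction descriptors + rotamer energy = 31 feature columns
  expect_length(setdiff(names(back), c("structure", "target")), 31)
  # empty vector list gives a header-only file
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(list(), f0)
  expect_equal(nrow(read_descriptor_table(f0)), 0)
  # mixed modes refuse to serialize
  ind <- aggregate_descriptors(det$hits, det$bridges, "individual")
  expect_error(write_descriptor_table(list(g, ind), f), "mixed")
})
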