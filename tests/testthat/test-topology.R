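test_that("canonical enumeration yields 8 distinct topologies, 12 with mixed", {
  tp8 <- enumerate_topologies(include_mixed = FALSE)
  expect_length(tp8, 8)
  expect_length(unique(vapply(tp8, format, character(1))), 8)
  expect_setequal(unique(vapply(tp8, function(t) t$mechanism, character(1))),
                  c("distributive", "processive"))

  tp12 <- enumerate_topologies(include_mixed = TRUE)
  expect_length(tp12, 12)
  expect_length(unique(vapply(tp12, format, character(1))), 12)
  mechs <- vapply(tp12, function(t) t$mechanism, character(1))
  expect_equal(sum(mechs == "mixed"), 4)
})

test_that("no positive-feedback target implies no feedback components", {
  tps <- enumerate_topologies(include_mixed = TRUE)
  for (tp in tps) {
    if (tp$positive_feedback == "none")
      expect_length(tp$feedback_components, 0)
    else
      expect_setequal(tp$feedback_components, c("affinity", "catalytic"))
  }
  expect_error(hog_topology("mixed", "none", feedback_components = "affinity"),
               "empty")
})

test_that("strain specification validates its fields", {
  expect_error(hog_strain(deletions = "HOG1"), "unknown deletion")
  expect_error(hog_strain(overexpression = c(Pbs2 = -1)), "> 0")
  expect_error(hog_strain(overexpression = 2), "named")
  s <- hog_strain(deletions = c("ptp2", "PTP3"), pbs2_s248 = "S248A")
  expect_setequal(s$deletions, c("PTP2", "PTP3"))
  expect_match(format(s), "S248A")
})

test_that("topology configs round-trip through YAML and JSON", {
  topo <- hog_topology("mixed", "pbs2", c("catalytic", "affinity"),
                       negative_feedback = FALSE, bounds = "physiological")
  strain <- hog_strain(deletions = "SHO1", overexpression = c(Pbs2 = 10))
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_topology_config(topo, f, strain = strain)
    back <- read_topology_config(f)
    expect_equal(back$topology, topo)
    expect_equal(back$strain$deletions, "SHO1")
    expect_equal(back$strain$overexpression, c(Pbs2 = 10))
  }
})
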