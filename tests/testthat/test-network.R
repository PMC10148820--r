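test_that("conserved totals are left null vectors of the stoichiometry matrix", {
  for (tp in enumerate_topologies(include_mixed = TRUE)) {
    net <- build_network(tp)
    S <- stoichiometry_matrix(net)
    for (prot in names(net$conserved)) {
      v <- as.numeric(rownames(S) %in% net$conserved[[prot]])
      expect_equal(max(abs(v %*% S)), 0,
                   info = paste(format(tp), prot, sep = " / "))
    }
  }
})

test_that("parameter table is consistent with the reaction list", {
  for (mech in c("mixed", "distributive", "processive")) {
    net <- build_network(hog_topology(mech))
    p <- net$parameters
    expect_false(any(duplicated(p$name)))
    expect_true(all(10^p$log10 > 0))
    expect_true(all(p$lower < p$upper))
    refs <- unique(unlist(lapply(net$reactions, `[[`, "params")))
    expect_true(all(refs %in% c(p$name, names(net$derived))))
  }
})

test_that("mechanism dictates the Hog1-Pbs2 reaction structure", {
  has_tag <- function(net, tag)
    any(vapply(net$reactions, function(r) identical(r$tag, tag), TRUE))
  np <- build_network(hog_topology("processive"))
  ## no reaction releases free mono-phospho Hog1 from the nascent complex
  expect_false(has_tag(np, "monophospho_dissociation"))
  expect_false("Pbs2PPHog1P_re" %in% np$species$name)

  nd <- build_network(hog_topology("distributive"))
  expect_false(has_tag(nd, "immediate_second_step"))
  expect_true(has_tag(nd, "monophospho_dissociation"))

  nm <- build_network(hog_topology("mixed"))
  expect_true(has_tag(nm, "immediate_second_step"))
  expect_true(has_tag(nm, "monophospho_dissociation"))
  expect_true(all(c("Pbs2PPHog1P", "Pbs2PPHog1P_feedback") %in%
                    nm$species$name))
  ## distinct second-step rates for base and feedback complexes
  expect_true(all(c("k_phospho", "k_phospho_feed") %in%
                    c(nm$parameters$name, names(nm$derived))))
})

test_that("feedback components without a target are rejected", {
  topo <- hog_topology("mixed", "pbs2")
  topo$positive_feedback <- "none"   # corrupt past the constructor
  expect_error(build_network(topo), "without a .*target")
})

test_that("strain application has deletion/overexpression semantics", {
  net <- build_network(hog_topology("mixed"))
  del <- apply_strain(net, hog_strain(deletions = "PBS2"))
  expect_true(all(del$species$init[del$species$name %in%
                                     del$conserved$Pbs2] == 0))
  ## input network unchanged
  expect_equal(net$species$init[net$species$name == "Pbs2"], 1)

  ox <- apply_strain(net, hog_strain(overexpression = c(Pbs2 = 10)))
  expect_equal(sum(ox$species$init[ox$species$name %in% ox$conserved$Pbs2]),
               10 * sum(net$species$init[net$species$name %in%
                                           net$conserved$Pbs2]))

  ## idempotent deletions; deletion and overexpression of different
  ## proteins commute
  del2 <- apply_strain(del, hog_strain(deletions = "PBS2"))
  expect_equal(del2$species$init, del$species$init)
  a <- apply_strain(apply_strain(net, hog_strain(deletions = "SHO1")),
                    hog_strain(overexpression = c(Pbs2 = 3)))
  b <- apply_strain(apply_strain(net, hog_strain(overexpression = c(Pbs2 = 3))),
                    hog_strain(deletions = "SHO1"))
  expect_equal(a$species$init, b$species$init)

  expect_error(apply_strain(build_basic_cascade("distributive"),
                            hog_strain(deletions = "PBS2")),
               "absent")
})

test_that("pbs2 deletion abolishes the Hog1-PP response to any stimulus", {
  net <- ref_net("mixed", hog_strain(deletions = "PBS2"))
  tr <- run_protocol(net, hog_protocol("step", 0.6, horizon = 1200),
                     tgrid = seq(0, 1200, 30))
  expect_true(tr$success)
  pp <- species_total(tr, c("Hog1PPc", "Hog1PPn"))
  expect_lt(max(pp), 1e-9)
})

test_that("S248 alleles edit the affinity feedback as specified", {
  net <- build_network(hog_topology("mixed"))
  a <- apply_strain(net, hog_strain(pbs2_s248 = "S248A"))
  expect_equal(a$parameters$log10[a$parameters$name == "fb_aff"], 0)
  e <- apply_strain(net, hog_strain(pbs2_s248 = "S248E"))
  conv <- Filter(function(r) identical(r$tag, "positive_feedback") &&
                   "Pbs2PP" %in% names(r$reactants), e$reactions)
  expect_length(conv, 1)
  expect_equal(conv[[1]]$kind, "mass_action")   # constitutive conversion
})

test_that("basic cascade conserves each tier and responds to input", {
  for (mech in c("distributive", "processive")) {
    net <- build_basic_cascade(mech)
    S <- stoichiometry_matrix(net)
    for (prot in names(net$conserved)) {
      v <- as.numeric(rownames(S) %in% net$conserved[[prot]])
      expect_equal(max(abs(v %*% S)), 0)
    }
  }
  ## distributive: free mono-phospho MAPK species exists
  expect_true("Kp" %in% build_basic_cascade("distributive")$species$name)
  ## processive: steady-state dose-response is monotone on a positive grid
  dr <- dose_response(build_basic_cascade("processive"),
                      seq(0.05, 1, length.out = 8), horizon = 600,
                      summary = "final")
  expect_true(all(diff(dr$response) > -1e-6))
})

test_that("reaction table export lists every reaction with its rate law", {
  net <- build_network(hog_topology("mixed"))
  lines <- write_reaction_table(net)
  expect_length(lines, length(net$reactions) + 1)
  expect_match(lines[1], "rate_law")
  expect_true(any(grepl("michaelis_menten", lines)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(net, f)
  expect_equal(readLines(f), as.character(lines))
})
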