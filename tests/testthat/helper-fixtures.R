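# shared fixtures, built once per test run and memoised

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  v <- get0(key, envir = .fix)
  if (is.null(v)) {
    v <- force(expr)
    assign(key, v, envir = .fix)
  }
  v
}

ref_net <- function(mech = "mixed", strain = NULL) {
  if (is.null(strain)) memo(paste0("net_", mech), hog_reference_network(mech))
  else hog_reference_network(mech, strain)
}

wt_step_traj <- function(mech = "mixed") {
  memo(paste0("traj_", mech),
       run_protocol(ref_net(mech), hog_protocol("step", 0.4, horizon = 2400),
                    tgrid = c(seq(0, 120, by = 5), seq(130, 2400, by = 10))))
}

# one simulated condition (wt, 0.4 M step), both MS modalities: cheap to fit
ms_catalogue <- function() {
  cat_ <- design_catalogue()
  cat_ <- cat_[cat_$dataset_id %in% c("ms_pp_fast", "ms_p_fast"), ]
  cat_$use <- "fit"
  cat_
}

ms_dataset <- function() {
  memo("ms_dataset",
       generate_dataset(ref_net("mixed"), ms_catalogue(), noise = TRUE,
                        seed = 42))
}
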