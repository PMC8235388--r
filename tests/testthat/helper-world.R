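# Shared fixtures, built in code.  The default toy world (3 regions x 4
# sectors x 2 factors, REG1 the dominant wheat exporter) is calibrated once
# and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

toy_params <- function(seed = 42) {
  key <- paste0("params_", seed)
  if (is.null(.fixture_cache[[key]])) {
    sam <- generate_sam(world_spec(seed = seed))
    .fixture_cache[[key]] <- calibrate(sam)
  }
  .fixture_cache[[key]]
}

sym_params <- function(seed = 7) {
  key <- paste0("sym_", seed)
  if (is.null(.fixture_cache[[key]])) {
    sp <- world_spec(regions = c("A", "B"), symmetric = TRUE,
                     export_share = 0.2, seed = seed)
    .fixture_cache[[key]] <- calibrate(generate_sam(sp))
  }
  .fixture_cache[[key]]
}

# region with the largest benchmark wheat import share (the "importer" in
# directional tests)
importer_of <- function(params) {
  w <- params$wheat_sector
  share <- params$M0agg[w, ] / params$Q0[w, ]
  names(which.max(share))
}

unit_shock <- function(params) {
  stats::setNames(rep(1, length(params$regions)), params$regions)
}
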