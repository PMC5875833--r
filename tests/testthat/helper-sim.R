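# shared fixtures: a compact 160x160 detector at the 0.784 mm pitch keeps
# the 10x10 cm field (100 mm at SID 1000) inside a 125 mm frame while
# reaching the same 0.0392 mm effective pitch as the clinical raster
test_cfg <- function(crossplane = 0, inplane = 0, noise = 0, seed = 1L,
                     d_epi = 1000, ...) {
  sim_config(geometry = linac_geometry(d_epi = d_epi),
             true_offset = offset_vector(crossplane, inplane),
             grid = c(160L, 160L), noise = noise, seed = seed, ...)
}

measure_sim <- function(cfg) {
  measure_focal_spot(render_measurement_set(cfg), cfg$geometry)
}

# Independent ray-trace oracle for the projection of one aperture edge:
# parameterise rays from the displaced source by slope, root-find the slope
# whose ray grazes the edge at the collimator plane, follow that ray to the
# detector. Shares no algebra with project_center/project_edges.
ray_trace_edge <- function(source_offset, edge, d_col, d_epi) {
  hit <- function(slope) source_offset + slope * d_col - edge
  sl <- stats::uniroot(hit, interval = c(-1, 1), tol = 1e-14)$root
  source_offset + sl * d_epi
}

ray_trace_center <- function(source_offset, edges, d_col, d_epi) {
  mean(vapply(edges, ray_trace_edge, numeric(1),
              source_offset = source_offset, d_col = d_col, d_epi = d_epi))
}
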