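# Shared solved cases, computed once per test run and reused across files.
.case_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- force(expr)
  .case_cache[[key]]
}

# straight-channel Poiseuille oracle case on a uniform grid
poiseuille_flow <- function(ny = 64) {
  cached(paste0("pois", ny), {
    case <- make_poiseuille_case(Y0 = 100, gamma0 = 1000)
    gr <- generate_grid(case$geom, nx = 32, ny = ny, cluster = 0, eta_cluster = 0)
    list(case = case, grid = gr,
         flow = solve_flow(case$geom, case$fluid, case$gamma0, gr))
  })
}

# default stenosis channel at moderate resolution (shared by many tests)
stenosis_flow <- function(placement = "eccentric", gamma0 = 1000,
                          S = 0.8, alpha = 85, nx = 144, ny = 36,
                          fluid = blood_newtonian()) {
  key <- paste("sten", placement, gamma0, S, alpha, nx, ny, fluid$name, sep = "_")
  cached(key, {
    geom <- stenosis_geometry(S = S, alpha = alpha, placement = placement)
    gr <- generate_grid(geom, nx, ny)
    fl <- solve_flow(geom, fluid, gamma0, gr)
    list(geom = geom, grid = gr, flow = fl)
  })
}

# shear map + platelet profile for a cached stenosis flow
stenosis_peaks <- function(...) {
  args <- list(...)
  key <- paste0("peaks_", paste(unlist(args), collapse = "_"))
  cached(key, {
    cs <- do.call(stenosis_flow, args)
    map <- shear_rate_field(cs$flow)
    pr <- platelet_trajectory_profile(cs$flow, map)
    list(map = map, profile = pr, flow = cs$flow)
  })
}

# acceptance-scale runs (resolution used for the quantitative contrasts)
acceptance_run <- function(placement, gamma0) {
  key <- paste0("acc_", placement, "_", gamma0)
  cached(key, {
    geom <- stenosis_geometry(S = 0.8, alpha = 85, placement = placement)
    gr <- generate_grid(geom, 240, 60)
    fl <- solve_flow(geom, blood_newtonian(), gamma0, gr)
    map <- shear_rate_field(fl)
    pr <- platelet_trajectory_profile(fl, map)
    list(flow = fl, map = map, profile = pr)
  })
}
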