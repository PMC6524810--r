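# data.table non-standard evaluation column names
utils::globalVariables(c(
  ".", ".N", ".SD", ".BY", "E", "Ebar", "amp", "annual", "base", "bin",
  "bin_effort", "bin_lo_km", "cell", "coarse_cell", "col", "count", "date",
  "day", "days", "dist_km", "dist_port_km", "dist_shore_km", "distance_km",
  "e", "e0", "e_n", "effort", "effort_per_day", "fleet", "frac", "gear",
  "gear_class", "grp_n", "hol_factor", "i.mean_shore_distance_nm", "implied",
  "in_eez", "is_fishing", "k", "lat", "lat_pos", "length_m", "lon",
  "lon_pos", "mean_shore_distance_nm", "month", "n", "n_cells", "nf",
  "peak", "rel", "rel_sd", "retained", "row", "s", "sd_rel", "si",
  "si_coarse", "si_fine", "total", "vd", "vessel_days", "vessel_id", "vidx",
  "year"
))
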