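# Shared fixtures, all generated in code.

LEADS <- c("pct_cells_gt3_puncta", "puncta_area_per_cell",
           "puncta_intensity_per_cell")

# A small clean screen with a couple of planted modulators.
tiny_screen <- function(seed = 1, n_plates = 2, replicates = 3, ...) {
  simulate_screen(screen_sim_config(
    n_plates = n_plates, replicates = replicates,
    planted_positive_modulators = c("g0001", "g0002"),
    planted_negative_modulators = c("g0003"),
    seed = seed, ...
  ))
}

# A manually built single-plate dataset whose readouts are fully controlled:
# `values` is a function(role, row, col) -> value applied to every well and
# every parameter (3 parameters, 1 plate, `replicates` replicates).
manual_screen <- function(values, replicates = 3, layout = "primary") {
  lay <- plate_layout(layout)
  rows <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    df <- lay$roles
    data.frame(plate_id = "P01", replicate = r, well = df$well,
               role = df$role,
               gene_id = ifelse(df$role == "sample",
                                paste0("g", df$well), NA_character_),
               sirna_id = ifelse(df$role == "sample",
                                 paste0("g", df$well), NA_character_),
               stringsAsFactors = FALSE)
  }))
  rr <- well_row(rows$well); cc <- well_col(rows$well)
  for (p in LEADS) {
    rows[[p]] <- mapply(values, rows$role, rr, cc, rows$replicate)
  }
  screen_dataset(rows, layout = layout, parameter_names = LEADS,
                 replicates_per_plate = replicates)
}

# control vectors with an exact scaled MAD of `mad` around `center`
mad_vector <- function(center, mad, n = 8) {
  d <- mad / 1.4826
  center + d * seq(-(n - 1) / 2, (n - 1) / 2, length.out = n) /
    stats::median(abs(seq(-(n - 1) / 2, (n - 1) / 2, length.out = n)))
}
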