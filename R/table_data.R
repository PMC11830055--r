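# Reference values for the comparison and effectiveness tables (presets
# table2 .. table9), transcribed once from the published tables so that
# reproduction runs need no external files.  Column "m" in the
# effectiveness tables is the tabulated modulus, entering the closed form
# as Phi^2 = m^2 (see effectiveness_sweep(modulus = "phi")).

ref_table2 <- function() {
  tibble::tribble(
    ~m, ~s1b, ~eta_m,
    0.1, 1.0, 0.999943,  0.1, 1.5, 0.722181,  0.1, 1.7, 0.656826,  0.1, 2.0, 0.583300,
    1, 1.0, 0.994334,    1, 1.8, 0.626062,    1, 2.3, 0.525988,    1, 2.7, 0.472616,
    5, 1.0, 0.858358,    5, 2.3, 0.454059,    5, 3.7, 0.336383,    5, 4.5, 0.302015,
    10, 1.0, 0.433430,   10, 4.0, 0.162536,   10, 7.0, 0.123837,   10, 13.0, 0.100022
  )
}

ref_table3 <- function() {
  tibble::tribble(
    ~m, ~theta, ~eta_m,
    0.1, 1.0, 0.999980,  0.1, 1.5, 0.999971,  0.1, 2.3, 0.999960,  0.1, 3.7, 0.999949,
    1, 1.0, 0.997960,    1, 1.7, 0.996766,    1, 4.5, 0.994538,    1, 7.1, 0.993732,
    5, 1.0, 0.949009,    5, 3.5, 0.876614,    5, 5.0, 0.858358,    5, 10.0, 0.831434,
    10, 1.0, 0.796035,   10, 4.7, 0.445295,   10, 8.3, 0.350161,   10, 17.0, 0.272273
  )
}

# comparison tables: `column` is the varied parameter value of each
# sub-table, `average` the printed column-average percentage error
ref_comparison <- function(id) {
  x <- seq(1, 2, 0.2)
  tab <- switch(
    id,
    table4 = list(
      by = "b0",
      cols = list(
        list(value = 8.68, average = 0.000152,
             hpm = c(0.983742, 0.985243, 0.988081, 0.991548, 0.995528, 1),
             numeric = c(0.983745, 0.985246, 0.988083, 0.991549, 0.995528, 1),
             pct = c(0.000305, 0.000304, 0.000202, 0.000101, 0, 0)),
        list(value = 34.72, average = 0,
             hpm = c(0.994948, 0.995603, 0.996495, 0.997525, 0.998693, 1),
             numeric = c(0.994948, 0.995603, 0.996495, 0.997525, 0.998693, 1),
             pct = c(0, 0, 0, 0, 0, 0)))),
    table5 = list(
      by = "b0",
      cols = list(
        list(value = 8.68, average = 0.000633,
             hpm = c(1.000698, 1.000583, 1.000414, 1.000244, 1.000100, 1),
             numeric = c(1.000699, 1.000599, 1.000426, 1.000251, 1.000102, 1),
             pct = c(0.000099, 0.001599, 0.001199, 0.000699, 0.000199, 0)),
        list(value = 34.72, average = 0,
             hpm = c(1.000056, 1.000043, 1.000028, 1.000015, 1.000005, 1),
             numeric = c(1.000056, 1.000043, 1.000028, 1.000015, 1.000005, 1),
             pct = c(0, 0, 0, 0, 0, 0)))),
    table6 = list(
      by = "phi2",
      cols = list(
        list(value = 1, average = 0.000201,
             hpm = c(0.992697, 0.993530, 0.994832, 0.996350, 0.998072, 1),
             numeric = c(0.992702, 0.993533, 0.994835, 0.996351, 0.998072, 1),
             pct = c(0.000504, 0.000302, 0.000302, 0.000100, 0, 0)),
        list(value = 10, average = 0.018978,
             hpm = c(0.929310, 0.937188, 0.949605, 0.964212, 0.980986, 1),
             numeric = c(0.929737, 0.937513, 0.949801, 0.964306, 0.981014, 1),
             pct = c(0.045948, 0.034678, 0.020640, 0.009749, 0.002854, 0)))),
    table7 = list(
      by = "phi2",
      cols = list(
        list(value = 1, average = 0.001681,
             hpm = c(1.001851, 1.001486, 1.000992, 1.000545, 1.000198, 1),
             numeric = c(1.001895, 1.001517, 1.001009, 1.000552, 1.000200, 1),
             pct = c(0.004392, 0.003095, 0.001698, 0.000699, 0.000199, 0)),
        list(value = 10, average = 0.012568,
             hpm = c(1.018490, 1.014835, 1.009894, 1.005427, 1.001968, 1),
             numeric = c(1.018812, 1.015069, 1.010027, 1.005486, 1.001985, 1),
             pct = c(0.031615, 0.023058, 0.013169, 0.005868, 0.001696, 0)))),
    table8 = list(
      by = "gamma",
      cols = list(
        list(value = 5, average = 0.000050,
             hpm = c(0.994733, 0.995334, 0.996274, 0.997369, 0.998611, 1),
             numeric = c(0.994734, 0.995335, 0.996275, 0.997369, 0.998611, 1),
             pct = c(0.000101, 0.000100, 0.000100, 0, 0, 0)),
        list(value = 10, average = 0.000134,
             hpm = c(0.994733, 0.995334, 0.996274, 0.997369, 0.998611, 1),
             numeric = c(0.994736, 0.995336, 0.996276, 0.997370, 0.998611, 1),
             pct = c(0.000302, 0.000201, 0.000201, 0.000100, 0, 0)))),
    table9 = list(
      by = "gamma",
      cols = list(
        list(value = 5, average = 0.000149,
             hpm = c(1.000619, 1.000499, 1.000335, 1.000186, 1.000068, 1),
             numeric = c(1.000623, 1.000502, 1.000337, 1.000186, 1.000068, 1),
             pct = c(0.000399, 0.000299, 0.000199, 0, 0, 0)),
        list(value = 10, average = 0.001249,
             hpm = c(1.001334, 1.001070, 1.000714, 1.000392, 1.000142, 1),
             numeric = c(1.001365, 1.001093, 1.000727, 1.000398, 1.000144, 1),
             pct = c(0.003096, 0.002298, 0.001299, 0.000599, 0.000199, 0)))),
    abort_dkr(paste0("unknown comparison table id: ", id),
              class = "dkrmr_error_config")
  )
  rows <- purrr::map_dfr(tab$cols, function(cl) {
    tibble::tibble(column = cl$value, x = x, hpm = cl$hpm,
                   numeric = cl$numeric, pct_error = cl$pct,
                   average_pct_error = cl$average)
  })
  attr(rows, "by") <- tab$by
  rows
}

#' Printed reference values for a comparison or effectiveness table
#'
#' Returns the transcribed printed values backing a preset: for `table2` /
#' `table3` columns `m` (tabulated modulus), `s1b` or `theta`, `eta_m`;
#' for `table4` .. `table9` columns `column` (the varied parameter value),
#' `x`, `hpm`, `numeric`, `pct_error`, `average_pct_error`.
#'
#' @param id One of `"table2"` .. `"table9"`.
#' @return A tibble of reference values.
#' @export
table_reference <- function(id) {
  switch(id,
         table2 = ref_table2(),
         table3 = ref_table3(),
         ref_comparison(id))
}
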