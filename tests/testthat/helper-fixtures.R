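# shared fixture builders; everything is generated in code

states_from <- function(t_bars) lapply(t_bars, state_from_t_bar)

# a small cross table with hand-controlled values
tiny_crosses <- function() {
  tibble::tibble(
    query_id = paste0("q", 1:5),
    array_id = paste0("a", 1:5),
    f_query  = c(0.7, 0.5, 0.3, 0.8, 0.6),
    f_array  = c(0.5, 0.5, 0.6, 0.2, 0.9),
    f_double = c(0.35, 0.25, 0.18, 0.16, 0.54),
    sd_double = rep(0.05, 5)
  )
}

write_cross_csv <- function(df, path) {
  readr::write_csv(df, path)
  path
}
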