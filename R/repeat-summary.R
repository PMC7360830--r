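#' Summarize repeat content per genome
#'
#' Combines the outputs of [find_ssrs()], [find_dispersed_repeats()] and
#' [find_tandem_repeats()] into the per-genome count table conventional in
#' plastome surveys: forward/reverse/complement counts with their subtotal,
#' palindromic and tandem counts and a grand total, plus SSR counts by unit
#' length and by motif.
#'
#' @param ssr an `ssr_table` (or NULL).
#' @param dispersed a `repeat_table` (or NULL).  Because the published cap
#'   of 100 on computed repeats can interact with the whole-IR self hit,
#'   both capped totals and totals excluding `is_ir` records are exposed.
#' @param tandem a `tandem_table` (or NULL).
#' @param id genome identifier for the row.
#' @return list with `counts` (one-row data.frame), `ssr_by_unit`,
#'   `ssr_by_motif` (data.frames).
#' @export
summarize_repeats <- function(ssr = NULL, dispersed = NULL, tandem = NULL,
                              id = "genome") {
  cat_count <- function(cat) {
    if (is.null(dispersed) || !nrow(dispersed)) return(0L)
    sum(dispersed$category == cat)
  }
  f <- cat_count("forward"); r <- cat_count("reverse")
  cc <- cat_count("complement"); pal <- cat_count("palindromic")
  pal_noir <- if (is.null(dispersed) || !nrow(dispersed)) 0L else
    sum(dispersed$category == "palindromic" & !dispersed$is_ir)
  tn <- if (is.null(tandem)) 0L else nrow(tandem)
  counts <- data.frame(
    id = id, forward = f, reverse = r, complement = cc,
    dispersed_subtotal = f + r + cc, palindromic = pal,
    palindromic_excl_ir = pal_noir, tandem = tn,
    total = f + r + cc + pal + tn,
    n_ssr = if (is.null(ssr)) 0L else nrow(ssr),
    stringsAsFactors = FALSE)
  by_unit <- data.frame(unit_len = 1:6, count = vapply(1:6, function(u)
    if (is.null(ssr) || !nrow(ssr)) 0L else sum(ssr$unit_len == u), 0L))
  by_motif <- if (is.null(ssr) || !nrow(ssr))
    data.frame(motif = character(), count = integer(),
               stringsAsFactors = FALSE)
  else {
    tb <- table(ssr$motif)
    data.frame(motif = names(tb), count = as.integer(tb),
               stringsAsFactors = FALSE)
  }
  list(counts = counts, ssr_by_unit = by_unit, ssr_by_motif = by_motif)
}
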