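# Motif-parameter summaries.
#
# Per-structure parameters (num_*) are averaged over the sample with
# population variance (divide by N), as in a descriptive table.  Per-motif
# parameters (unp_h, bps_m, ...) pool motif instances across the whole
# sample by default; per-structure means are available behind a flag since
# the alternative reading is also defensible.  Parameters that are
# structurally constant or undefined (unp_s, unp_hel, bps_h) are reported
# as NA, mirroring the "--" cells of the usual presentation.

summary_parameters <- function() c(
  "num_unp", "num_bps", "num_urs",
  "num_e", "num_h", "num_s", "num_b", "num_i", "num_m", "num_hel",
  "unp_e", "unp_h", "unp_s", "unp_b", "unp_i", "unp_m", "unp_hel",
  "bps_e", "bps_h", "bps_s", "bps_b", "bps_i", "bps_m", "bps_hel")

pop_var <- function(x) {
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Expectation and variance of structural-motif parameters
#'
#' @param sample nonempty list of \code{secstruct} (or bar-bracket strings).
#' @param pool_instances if TRUE (default) per-motif parameters pool motif
#'   instances over the whole sample; if FALSE they are per-structure means
#'   of instance values.
#' @return a data.frame (class \code{summary_table}) with one row per
#'   parameter: mean, variance, and the number of observations pooled.
#' @export
summarize_motifs <- function(sample, pool_instances = TRUE) {
  if (length(sample) == 0) stop("empty sample")
  profs <- lapply(sample, decompose_motifs)
  getn <- function(field) vapply(profs, function(p) as.numeric(p[[field]]), 0)
  rows <- list()
  add_row <- function(name, values) {
    rows[[name]] <<- data.frame(parameter = name,
                                mean = if (length(values)) mean(values) else NA_real_,
                                variance = pop_var(values),
                                n_obs = length(values))
  }
  for (f in c("num_unp", "num_bps", "num_urs", "num_e", "num_h", "num_s",
              "num_b", "num_i", "num_m", "num_hel"))
    add_row(f, getn(f))
  inst <- function(field) {
    if (pool_instances) unlist(lapply(profs, `[[`, field))
    else vapply(profs, function(p) {
      v <- p[[field]]
      if (length(v)) mean(v) else NA_real_
    }, 0)
  }
  drop_na <- function(x) x[!is.na(x)]
  add_row("unp_e", getn("unp_e"))            # one exterior loop per structure
  add_row("unp_h", drop_na(inst("hairpin_sizes")))
  add_row("unp_s", numeric(0))               # stacked pairs hold no unpaired
  add_row("unp_b", drop_na(inst("bulge_sizes")))
  add_row("unp_i", drop_na(inst("interior_sizes")))
  add_row("unp_m", drop_na(inst("multi_unp")))
  add_row("unp_hel", numeric(0))             # undefined
  add_row("bps_e", getn("bps_e"))
  add_row("bps_h", numeric(0))               # undefined
  add_row("bps_s", rep(1, sum(getn("num_s"))))
  add_row("bps_b", rep(1, sum(getn("num_b"))))
  add_row("bps_i", rep(1, sum(getn("num_i"))))
  add_row("bps_m", drop_na(inst("multi_branches")))
  add_row("bps_hel", drop_na(inst("helix_lengths")))
  out <- do.call(rbind, rows[summary_parameters()])
  rownames(out) <- NULL
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Size-matched random sample for a native database
#'
#' For each native structure, draws exactly one random structure of the same
#' size, so native and random samples agree size by size. Native sizes below
#' the minimum structure size 5 are skipped with a warning.
#'
#' @param db list of native \code{secstruct}.
#' @param spec an \code{adm_spec}.
#' @param table size table built to the maximum native size.
#' @param order scan order.
#' @param seed optional seed.
#' @return list of sampled \code{secstruct}, one per usable native structure,
#'   with the native sizes as attribute \code{"sizes"}.
#' @export
size_matched_sample <- function(db, spec, table,
                                order = c("boustrophedon", "sequential"),
                                seed = NULL) {
  order <- match.arg(order)
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(db, function(s) s$length, 0L)
  usable <- sizes >= 5
  if (any(!usable))
    warning(sum(!usable), " native structure(s) below size 5 skipped")
  out <- lapply(sizes[usable], function(n) {
    total <- class_size(spec, spec$root, n, table)
    word <- unrank_rec(spec, table, spec$root, n, random_rank(total),
                       order, NULL)
    parse_dotbracket(word)
  })
  attr(out, "sizes") <- sizes[usable]
  out
}

#' Compare motif summaries of two samples
#'
#' @param native,random two structure samples.
#' @param pool_instances see \code{\link{summarize_motifs}}.
#' @return data.frame with means and variances of both samples side by side.
#' @export
compare_samples <- function(native, random, pool_instances = TRUE) {
  a <- summarize_motifs(native, pool_instances)
  b <- summarize_motifs(random, pool_instances)
  data.frame(parameter = a$parameter,
             mean_random = b$mean, mean_native = a$mean,
             var_random = b$variance, var_native = a$variance)
}

#' Write a summary (or comparison) table as TSV
#' @param x a data.frame.
#' @param path output file.
#' @export
write_summary_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
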