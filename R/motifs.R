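# Motif decomposition.
#
# Every base pair closes exactly one loop: a hairpin (no nested pair), a
# stacked pair (one nested pair, no unpaired bases on either side), a bulge
# (one nested pair, unpaired bases on exactly one side), an interior loop
# (one nested pair, unpaired bases on both sides) or a multiloop (>= 2
# nested pairs).  A helix is a maximal chain of stacked pairs plus its
# terminal pair, so an isolated pair is a helix of one pair.  The exterior
# loop is the unique top-level region.

#' Decompose a structure into its loop motifs
#'
#' @param s a \code{secstruct} (or a bar-bracket string, parsed on the fly).
#' @return an object of class \code{motif_profile}: per-structure counters
#'   (num_unp, num_bps, num_urs, num_e, num_h, num_s, num_b, num_i, num_m,
#'   num_hel), per-motif unpaired totals (unp_e/h/b/i/m), helix-adjacency
#'   totals (bps_e, bps_m, bps_hel) and the per-instance size vectors the
#'   summary statistics pool over.
#' @examples
#' decompose_motifs("(|||)")
#' @export
decompose_motifs <- function(s) {
  if (is.character(s)) s <- parse_dotbracket(s)
  partner <- s$partner
  n <- s$length
  chars <- strsplit(s$word, "")[[1]]

  # children pair-opens and bar gaps of the exclusive region (i, j), 0-based
  region <- function(i, j) {
    kids <- integer(0); gaps <- integer(0); bars <- 0L; k <- i
    while (k < j) {
      if (partner[k + 1] < 0) { bars <- bars + 1L; k <- k + 1L }
      else { gaps <- c(gaps, bars); bars <- 0L; kids <- c(kids, k); k <- partner[k + 1] + 1L }
    }
    list(kids = kids, gaps = c(gaps, bars))
  }

  opens <- s$pairs[, "open"]
  kind <- character(length(opens))          # loop type closed by each pair
  names(kind) <- as.character(opens)
  hairpin_sizes <- integer(0); bulge_sizes <- integer(0)
  interior_sizes <- integer(0); multi_unp <- integer(0); multi_branches <- integer(0)
  stack_parent <- logical(length(opens))    # pair is the inner pair of a stack
  names(stack_parent) <- as.character(opens)

  for (idx in seq_along(opens)) {
    i <- opens[idx]; j <- partner[i + 1]
    rg <- region(i + 1, j)
    k <- length(rg$kids)
    if (k == 0) {
      kind[idx] <- "hairpin"
      hairpin_sizes <- c(hairpin_sizes, rg$gaps[1])
    } else if (k == 1) {
      l <- rg$gaps[1]; r <- rg$gaps[2]
      if (l == 0 && r == 0) {
        kind[idx] <- "stack"
        stack_parent[as.character(rg$kids[1])] <- TRUE
      } else if (l == 0 || r == 0) {
        kind[idx] <- "bulge"
        bulge_sizes <- c(bulge_sizes, l + r)
      } else {
        kind[idx] <- "interior"
        interior_sizes <- c(interior_sizes, l + r)
      }
    } else {
      kind[idx] <- "multiloop"
      multi_unp <- c(multi_unp, sum(rg$gaps))
      multi_branches <- c(multi_branches, k)
    }
  }

  # helices: outermost pair = not the inner pair of a stacked outer pair
  helix_lengths <- integer(0)
  for (idx in seq_along(opens)) {
    if (stack_parent[idx]) next
    len <- 1L; cur <- idx
    while (kind[cur] == "stack") {
      len <- len + 1L
      inner_open <- opens[cur] + 1L
      cur <- match(inner_open, opens)
    }
    helix_lengths <- c(helix_lengths, len)
  }

  ext <- region(0, n)
  runs <- rle(chars == "|")
  profile <- list(
    num_unp = sum(chars == "|"),
    num_bps = length(opens),
    num_urs = sum(runs$values),
    num_e = 1L,
    num_h = sum(kind == "hairpin"),
    num_s = sum(kind == "stack"),
    num_b = sum(kind == "bulge"),
    num_i = sum(kind == "interior"),
    num_m = sum(kind == "multiloop"),
    num_hel = length(helix_lengths),
    unp_e = sum(ext$gaps),
    unp_h = sum(hairpin_sizes),
    unp_b = sum(bulge_sizes),
    unp_i = sum(interior_sizes),
    unp_m = sum(multi_unp),
    bps_e = length(ext$kids),          # helices adjacent to the exterior loop
    bps_m = sum(multi_branches),       # branch helices inside multiloops
    bps_hel = length(opens),           # pairs summed over helices
    hairpin_sizes = hairpin_sizes,
    bulge_sizes = bulge_sizes,
    interior_sizes = interior_sizes,
    multi_unp = multi_unp,
    multi_branches = multi_branches,
    helix_lengths = helix_lengths)
  class(profile) <- "motif_profile"
  profile
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf(paste0("<motif_profile> unp %d bps %d | h %d s %d b %d i %d ",
                     "m %d hel %d urs %d\n"),
              x$num_unp, x$num_bps, x$num_h, x$num_s, x$num_b, x$num_i,
              x$num_m, x$num_hel, x$num_urs))
  invisible(x)
}
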