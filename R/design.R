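#' Describe an MA field experiment design
#'
#' Encodes the replication structure of a mutation-accumulation field
#' assay: randomized complete blocks, MA lines with nested field sublines,
#' progenitor (founder) sublines, an optional reference accession (Col-0),
#' and the number of generations of mutation accumulation separating the
#' MA lines from the founder.
#'
#' The default values reproduce the published study design: 14 blocks,
#' 100 MA lines with 3-5 field sublines each and 5 plants per line per
#' block, 6 progenitor sublines with 6 plants each per block, no Col-0,
#' and t = 25 generations — 536 plants per block, 7,504 plants in total.
#'
#' @param n_blocks Number of field blocks.
#' @param n_ma_lines Number of MA lines.
#' @param progenitor_sublines Number of progenitor (founder) sublines.
#' @param field_sublines_per_line Length-2 integer range; each MA line is
#'   assigned a number of field sublines drawn uniformly from this range.
#' @param ma_plants_per_line_per_block Plants per MA line in each block.
#' @param progenitor_plants_per_subline_per_block Plants per progenitor
#'   subline in each block.
#' @param col0_plants_per_block Reference-accession plants per block
#'   (0 when the accession is absent).
#' @param t_generations Generations of mutation accumulation (t).
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design()
#' total_plants(d)  # 7504
#' @export
experiment_design <- function(n_blocks = 14,
                              n_ma_lines = 100,
                              progenitor_sublines = 6,
                              field_sublines_per_line = c(3, 5),
                              ma_plants_per_line_per_block = 5,
                              progenitor_plants_per_subline_per_block = 6,
                              col0_plants_per_block = 0,
                              t_generations = 25) {
  counts <- c(n_blocks, n_ma_lines, progenitor_sublines,
              ma_plants_per_line_per_block,
              progenitor_plants_per_subline_per_block,
              col0_plants_per_block, t_generations)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop_mutaccum("design counts must be non-negative integers",
                  "mutaccum_spec_error")
  if (t_generations < 1)
    stop_mutaccum("t_generations must be >= 1", "mutaccum_spec_error")
  if (length(field_sublines_per_line) == 1L)
    field_sublines_per_line <- rep(field_sublines_per_line, 2L)
  if (length(field_sublines_per_line) != 2L ||
      any(field_sublines_per_line < 1) ||
      field_sublines_per_line[1] > field_sublines_per_line[2])
    stop_mutaccum("field_sublines_per_line must be a valid positive range",
                  "mutaccum_spec_error")
  structure(list(
    n_blocks = as.integer(n_blocks),
    n_ma_lines = as.integer(n_ma_lines),
    progenitor_sublines = as.integer(progenitor_sublines),
    field_sublines_per_line = as.integer(field_sublines_per_line),
    ma_plants_per_line_per_block = as.integer(ma_plants_per_line_per_block),
    progenitor_plants_per_subline_per_block =
      as.integer(progenitor_plants_per_subline_per_block),
    col0_plants_per_block = as.integer(col0_plants_per_block),
    t_generations = as.integer(t_generations)
  ), class = "experiment_design")
}

#' Plants per block implied by a design
#' @param design An [experiment_design()].
#' @return Integer count of plants in one block.
#' @export
plants_per_block <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  design$n_ma_lines * design$ma_plants_per_line_per_block +
    design$progenitor_sublines * design$progenitor_plants_per_subline_per_block +
    design$col0_plants_per_block
}

#' Total plants implied by a design
#' @param design An [experiment_design()].
#' @return Integer count of plants across all blocks.
#' @export
total_plants <- function(design) design$n_blocks * plants_per_block(design)

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_design> %d blocks x (%d MA lines x %d plants + ",
    "%d progenitor sublines x %d plants + %d col0) = %d plants; t = %d\n"),
    x$n_blocks, x$n_ma_lines, x$ma_plants_per_line_per_block,
    x$progenitor_sublines, x$progenitor_plants_per_subline_per_block,
    x$col0_plants_per_block, total_plants(x), x$t_generations))
  invisible(x)
}
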