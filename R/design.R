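#' Build a pseudorandomized base/probe block design
#'
#' Constructs the 16-block passive-viewing run layout: base and probe blocks
#' strictly alternate (the run opens with a base block), and the eight probe
#' blocks form two cycles, each cycle a seeded permutation of the four probe
#' types for the scan dimension -- `{good,bad} x {left,right}` in GB scans,
#' `{novel,familiar} x {left,right}` in NF scans -- so that within every four
#' consecutive probe blocks each type occurs exactly once.
#'
#' @param scan_type `"GB"` (learned value) or `"NF"` (perceptual novelty).
#' @param seed Integer seed controlling the probe-type permutations and the
#'   excluded-block draw.
#' @param tr_s Seconds per volume (repetition time).
#' @param block_s Seconds per block.
#' @param n_blocks Total number of blocks (must be even).
#' @param stim_on_ms,stim_off_ms Stimulus flash timing within probe blocks
#'   (recorded in the design; stimuli are modeled at block resolution).
#' @param n_discard_trs Initial volumes excluded from regression
#'   (scanner magnetization transient).
#' @param exclude_rate Probability that a block is flagged excluded
#'   (emulating blocks lost to broken fixation); default 0.
#' @return An object of class `scan_design` with the block table, an
#'   event table (see [design_events()]), and timing fields.
#' @examples
#' d <- make_design("GB", seed = 1)
#' n_volumes(d)  # 192 at defaults
#' @export
make_design <- function(scan_type = c("GB", "NF"), seed = 1,
                        tr_s = 2.5, block_s = 30, n_blocks = 16,
                        stim_on_ms = 600, stim_off_ms = 200,
                        n_discard_trs = 3, exclude_rate = 0) {
  scan_type <- match.arg(scan_type)
  stopifnot(tr_s > 0, block_s > 0, n_blocks >= 2, n_blocks %% 2 == 0,
            exclude_rate >= 0, exclude_rate < 1)
  vols_per_block <- block_s / tr_s
  if (abs(vols_per_block - round(vols_per_block)) > 1e-9) {
    stop("block_s must be an integer multiple of tr_s")
  }
  vols_per_block <- as.integer(round(vols_per_block))

  types <- if (scan_type == "GB") c("good", "bad") else c("novel", "familiar")
  probe_types <- as.vector(outer(types, c("left", "right"),
                                 function(ty, h) paste(ty, h, sep = "_")))
  n_probe <- n_blocks / 2L
  n_cycles <- n_probe / 4L
  if (n_probe %% 4 != 0) stop("number of probe blocks must be a multiple of 4")

  probe_seq <- with_seed(seed, {
    unlist(lapply(seq_len(n_cycles), function(i) sample(probe_types)))
  })
  excluded <- with_seed(seed + 1L, {
    stats::runif(n_blocks) < exclude_rate
  })

  block_type <- rep(c("base", "probe"), n_blocks / 2L)
  trial_type <- ifelse(block_type == "base", "base", NA_character_)
  trial_type[block_type == "probe"] <- probe_seq
  blocks <- data.frame(
    block = seq_len(n_blocks),
    onset = (seq_len(n_blocks) - 1) * block_s,
    duration = block_s,
    block_type = block_type,
    trial_type = trial_type,
    hemifield = ifelse(block_type == "probe",
                       sub("^.*_", "", trial_type), NA_character_),
    excluded = excluded,
    stringsAsFactors = FALSE
  )

  structure(list(
    scan_type = scan_type, tr_s = tr_s, block_s = block_s,
    n_blocks = n_blocks, vols_per_block = vols_per_block,
    probe_types = probe_types, cycle_order = probe_seq,
    stim_on_ms = stim_on_ms, stim_off_ms = stim_off_ms,
    n_discard_trs = n_discard_trs, blocks = blocks, seed = seed
  ), class = "scan_design")
}

#' Total number of volumes in a scan design
#' @param design A `scan_design`.
#' @return Integer volume count (`n_blocks * block_s / tr_s`).
#' @export
n_volumes <- function(design) {
  stopifnot(inherits(design, "scan_design"))
  as.integer(design$n_blocks * design$vols_per_block)
}

#' Event table of a design (BIDS-style)
#'
#' One row per block with `onset` and `duration` in seconds, `trial_type`
#' (`"base"` or `"<type>_<hemifield>"`), `hemifield`, and the `excluded` flag.
#'
#' @param design A `scan_design`.
#' @return A data frame.
#' @export
design_events <- function(design) {
  stopifnot(inherits(design, "scan_design"))
  design$blocks
}

#' Map each volume to its block index
#' @param design A `scan_design`.
#' @return Integer vector of length [n_volumes()].
#' @export
volume_blocks <- function(design) {
  rep(seq_len(design$n_blocks), each = design$vols_per_block)
}

#' @export
print.scan_design <- function(x, ...) {
  cat(sprintf("<scan_design> %s: %d blocks x %gs (TR %gs, %d volumes)\n",
              x$scan_type, x$n_blocks, x$block_s, x$tr_s, n_volumes(x)))
  cat("probe order:", paste(x$cycle_order, collapse = ", "), "\n")
  invisible(x)
}

#' Write an event table to a tab-separated file
#' @param design A `scan_design`.
#' @param path Output path.
#' @export
write_events_tsv <- function(design, path) {
  utils::write.table(design_events(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table from a tab-separated file
#' @param path Path to a TSV written by [write_events_tsv()].
#' @return A data frame of events.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
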