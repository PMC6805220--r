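#' The eight-picture stimulus hierarchy
#'
#' Stimuli form a fixed 2 x 2 x 2 hierarchy: two categories (object, scene),
#' two subcategories per category (living/inanimate objects; indoor/outdoor
#' scenes), and two picture exemplars per subcategory. Pairs of trials are
#' later scored by relatedness level: same exemplar (SE), same subcategory
#' (SS), same category (SC), or different category (DC).
#'
#' @return data.frame of class \code{stim_hierarchy} with columns
#'   \code{exemplar}, \code{subcategory}, \code{category} (8 rows).
#' @examples
#' h <- stimulus_hierarchy()
#' table(h$category)
#' @export
stimulus_hierarchy <- function() .stim_hierarchy

.stim_hierarchy <- local({
  h <- data.frame(
    exemplar    = c("rabbit", "dog", "umbrella", "teapot",
                    "office", "bedroom", "beach", "forest"),
    subcategory = rep(c("living", "inanimate", "indoor", "outdoor"), each = 2),
    category    = rep(c("object", "scene"), each = 4),
    stringsAsFactors = FALSE
  )
  class(h) <- c("stim_hierarchy", "data.frame")
  h
})

#' Relatedness levels, ordered from most to least related
#' @export
relatedness_levels <- function() c("SE", "SS", "SC", "DC")

#' Relatedness level of a pair of exemplars
#'
#' SE if the two exemplars are identical, SS if they share a subcategory
#' but differ, SC if they share only the category, DC otherwise.
#'
#' @param a,b exemplar ids (vectorised; recycled to common length).
#' @param hierarchy a \code{\link{stimulus_hierarchy}}.
#' @return factor with levels SE, SS, SC, DC.
#' @examples
#' relatedness_level("umbrella", c("umbrella", "teapot", "rabbit", "office"))
#' @export
relatedness_level <- function(a, b, hierarchy = stimulus_hierarchy()) {
  ia <- match(a, hierarchy$exemplar)
  ib <- match(b, hierarchy$exemplar)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(a[is.na(ia)], b[is.na(ib)]))
    stop("unknown exemplar id(s): ", paste(bad, collapse = ", "))
  }
  n <- max(length(ia), length(ib))
  ia <- rep_len(ia, n); ib <- rep_len(ib, n)
  lev <- ifelse(ia == ib, "SE",
         ifelse(hierarchy$subcategory[ia] == hierarchy$subcategory[ib], "SS",
         ifelse(hierarchy$category[ia] == hierarchy$category[ib], "SC", "DC")))
  factor(lev, levels = relatedness_levels())
}

# random derangement of labels 1..n by rejection (internal)
.derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Build study lists of paired associates
#'
#' Assigns \code{n_pairs} trial-unique adjectives to pictures and splits
#' them into \code{n_lists} study lists, each balanced with
#' \code{n_pairs / n_lists / 8} pairs per picture. Within each list, half
#' the pairs are flagged to be tested intact and half recombined.
#' Recombined pairs are re-paired by a derangement of the eight picture
#' identities applied to the recombined subset, so no adjective keeps its
#' studied picture and the per-picture balance is preserved at test.
#'
#' @param hierarchy a \code{\link{stimulus_hierarchy}}.
#' @param n_pairs total number of paired associates (default 192).
#' @param n_lists number of study lists (default 3).
#' @param seed optional RNG seed.
#' @param counterbalance 1 or 2; version 2 swaps the intact/recombined
#'   assignment so that across the two versions every pair is tested once
#'   intact and once recombined.
#' @return data.frame with one row per pair: \code{adjective},
#'   \code{picture}, \code{subcategory}, \code{category}, \code{list},
#'   \code{status} (intact/recombined), \code{test_picture} (the picture
#'   shown at test: the studied one for intact pairs, the re-paired one
#'   for recombined pairs).
#' @export
make_lists <- function(hierarchy = stimulus_hierarchy(), n_pairs = 192L,
                       n_lists = 3L, seed = NULL, counterbalance = 1L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(counterbalance %in% 1:2)
  n_pairs <- as.integer(n_pairs); n_lists <- as.integer(n_lists)
  if (n_pairs %% n_lists != 0L)
    stop("n_pairs must be divisible by n_lists")
  per_list <- n_pairs %/% n_lists
  n_pic <- nrow(hierarchy)
  if (per_list %% n_pic != 0L)
    stop("pairs per list (", per_list, ") must be divisible by ", n_pic)
  per_pic <- per_list %/% n_pic
  if (per_list %% 2L != 0L || (per_pic %% 2L != 0L && per_list > n_pic))
    stop("need an even split of each list into intact and recombined halves")

  adjectives <- sprintf("adj_%04d", seq_len(n_pairs))
  rows <- vector("list", n_lists)
  for (l in seq_len(n_lists)) {
    pics <- rep(hierarchy$exemplar, per_pic)
    adj <- adjectives[(l - 1L) * per_list + seq_len(per_list)]
    # random adjective-picture pairing within the list
    pics <- sample(pics)
    df <- data.frame(adjective = adj, picture = pics, list = l,
                     stringsAsFactors = FALSE)
    # split each picture's pairs evenly into intact and recombined
    df$status <- "intact"
    for (p in hierarchy$exemplar) {
      ip <- which(df$picture == p)
      take <- sample(ip, length(ip) %/% 2L)
      df$status[take] <- "recombined"
    }
    if (counterbalance == 2L)
      df$status <- ifelse(df$status == "intact", "recombined", "intact")
    # derange picture identities over the recombined subset
    der <- .derangement(n_pic)
    remap <- setNames(hierarchy$exemplar[der], hierarchy$exemplar)
    df$test_picture <- ifelse(df$status == "recombined",
                              remap[df$picture], df$picture)
    rows[[l]] <- df
  }
  out <- do.call(rbind, rows)
  m <- match(out$picture, hierarchy$exemplar)
  out$subcategory <- hierarchy$subcategory[m]
  out$category <- hierarchy$category[m]
  rownames(out) <- NULL
  out[, c("adjective", "picture", "subcategory", "category",
          "list", "status", "test_picture")]
}

# run lengths of consecutive equal values (internal)
.max_run <- function(x) if (length(x) == 0L) 0L else max(rle(as.character(x))$lengths)

# check the sequencing constraints; returns TRUE/FALSE (internal)
.sequence_ok <- function(category, picture, status = NULL) {
  if (.max_run(category) > 4L) return(FALSE)
  if (.max_run(picture) > 2L) return(FALSE)
  if (!is.null(status) && .max_run(status) > 4L) return(FALSE)
  TRUE
}

#' Pseudo-random trial sequencing under adjacency constraints
#'
#' Orders the trials of one run by rejection sampling (full reshuffle on
#' any violation) so that (i) no more than four trials from the same
#' stimulus category occur in sequence, (ii) no picture appears more than
#' twice in a row, and, for test runs only, (iii) no more than four intact
#' or recombined trials occur in sequence. A full reshuffle on rejection
#' keeps the accepted order uniform over all valid orders.
#'
#' @param trials data.frame with columns \code{category}, \code{picture}
#'   (for test runs the picture label shown at test) and, when
#'   \code{phase = "test"}, \code{status}.
#' @param phase \code{"study"} or \code{"test"}.
#' @param seed optional RNG seed.
#' @param max_attempts reshuffles before giving up (default 10000).
#' @return \code{trials} reordered; the attempt count is attached as
#'   attribute \code{"attempts"}.
#' @export
sequence_trials <- function(trials, phase = c("study", "test"), seed = NULL,
                            max_attempts = 10000L) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  pic_col <- if (phase == "test" && "test_picture" %in% names(trials))
    "test_picture" else "picture"
  need <- c("category", pic_col, if (phase == "test") "status")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lacks column(s): ", paste(miss, collapse = ", "))
  for (attempt in seq_len(max_attempts)) {
    ord <- sample.int(nrow(trials))
    cat_seq <- trials$category[ord]
    if (phase == "test") {
      m <- match(trials[[pic_col]][ord], stimulus_hierarchy()$exemplar)
      cat_seq <- stimulus_hierarchy()$category[m]
    }
    ok <- .sequence_ok(cat_seq, trials[[pic_col]][ord],
                       if (phase == "test") trials$status[ord])
    if (ok) {
      out <- trials[ord, , drop = FALSE]
      rownames(out) <- NULL
      attr(out, "attempts") <- attempt
      return(out)
    }
  }
  stop("no valid order found in ", max_attempts, " attempts")
}

#' Build per-run event tables for the study and test phases
#'
#' Lays sequenced trials onto the scanner clock: stimulus duration 5 s,
#' inter-trial interval 1 s (SOA 6 s), first onset at \code{start_s}.
#'
#' @param pairs output of \code{\link{make_lists}}.
#' @param seed optional RNG seed controlling trial order.
#' @param start_s onset of the first trial in seconds (default 12).
#' @param duration_s,iti_s trial duration and inter-trial interval.
#' @return data.frame of class \code{event_table} with one row per trial:
#'   \code{run} (1-6, study runs odd-phase first), \code{phase},
#'   \code{block} (1-3), \code{trial}, \code{onset}, \code{duration},
#'   stimulus descriptors and \code{status}; \code{response}/\code{outcome}
#'   columns are NA until filled by the simulator or real data.
#' @export
build_event_tables <- function(pairs, seed = NULL, start_s = 12,
                               duration_s = 5, iti_s = 1) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- sort(unique(pairs$list))
  out <- vector("list", 2L * length(blocks))
  run <- 0L
  for (b in blocks) {
    lp <- pairs[pairs$list == b, , drop = FALSE]
    for (ph in c("study", "test")) {
      run <- run + 1L
      seq_b <- sequence_trials(lp, phase = ph)
      n <- nrow(seq_b)
      df <- data.frame(
        run = run, phase = ph, block = b, trial = seq_len(n),
        onset = start_s + (seq_len(n) - 1L) * (duration_s + iti_s),
        duration = duration_s,
        adjective = seq_b$adjective,
        picture = if (ph == "study") seq_b$picture else seq_b$test_picture,
        studied_picture = seq_b$picture,
        subcategory = seq_b$subcategory,
        category = seq_b$category,
        status = if (ph == "study") NA_character_ else seq_b$status,
        response = NA_character_, outcome = NA_character_,
        stringsAsFactors = FALSE
      )
      # descriptors follow the picture actually shown
      m <- match(df$picture, stimulus_hierarchy()$exemplar)
      df$subcategory <- stimulus_hierarchy()$subcategory[m]
      df$category <- stimulus_hierarchy()$category[m]
      out[[run]] <- df
    }
  }
  ev <- do.call(rbind, out)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Localizer run event schedule
#'
#' One functional localizer run in which each of the eight pictures is
#' shown \code{n_reps} times (default 12, giving 96 events; duration 4 s,
#' inter-stimulus interval 1 s). The order is pseudo-randomised under the
#' same adjacency constraints as the study phase.
#'
#' @param hierarchy a \code{\link{stimulus_hierarchy}}.
#' @param n_reps presentations per picture (default 12).
#' @param seed optional RNG seed.
#' @param start_s,duration_s,isi_s timing parameters.
#' @return an \code{event_table} with one row per localizer event.
#' @export
localizer_events <- function(hierarchy = stimulus_hierarchy(), n_reps = 12L,
                             seed = NULL, start_s = 12, duration_s = 4,
                             isi_s = 1) {
  if (!is.null(seed)) set.seed(seed)
  trials <- data.frame(
    picture = rep(hierarchy$exemplar, n_reps),
    stringsAsFactors = FALSE)
  m <- match(trials$picture, hierarchy$exemplar)
  trials$subcategory <- hierarchy$subcategory[m]
  trials$category <- hierarchy$category[m]
  seq_t <- sequence_trials(trials, phase = "study")
  n <- nrow(seq_t)
  ev <- data.frame(
    run = 1L, phase = "localizer", block = 1L, trial = seq_len(n),
    onset = start_s + (seq_len(n) - 1L) * (duration_s + isi_s),
    duration = duration_s, adjective = NA_character_,
    picture = seq_t$picture, studied_picture = seq_t$picture,
    subcategory = seq_t$subcategory, category = seq_t$category,
    status = NA_character_, response = NA_character_,
    outcome = NA_character_, stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write one run's events as a BIDS-style tab-separated file
#'
#' Columns: onset, duration, trial_type (phase), stimulus, subcategory,
#' category, status, response, outcome.
#'
#' @param events an \code{event_table} (one run).
#' @param path output \code{.tsv} path.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(length(unique(events$run)) == 1L)
  df <- data.frame(onset = events$onset, duration = events$duration,
                   trial_type = events$phase, stimulus = events$picture,
                   subcategory = events$subcategory, category = events$category,
                   status = events$status, response = events$response,
                   outcome = events$outcome, stringsAsFactors = FALSE)
  df[is.na(df)] <- "n/a"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV written by \code{\link{write_events_tsv}}
#' @param path file path.
#' @param run run index to attach.
#' @return an \code{event_table} for one run.
#' @export
read_events_tsv <- function(path, run = 1L) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "n/a")
  ev <- data.frame(run = run, phase = df$trial_type, block = NA_integer_,
                   trial = seq_len(nrow(df)), onset = df$onset,
                   duration = df$duration, adjective = NA_character_,
                   picture = df$stimulus, studied_picture = NA_character_,
                   subcategory = df$subcategory, category = df$category,
                   status = df$status, response = df$response,
                   outcome = df$outcome, stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}
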