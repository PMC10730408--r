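# Stimulus timeline for the four-assay behavioral paradigm.
#
# A protocol is an ordered list of assay blocks (VMR, LF, DF, ASR). Each
# block owns a frame rate, a post-stimulus recording window, and an ordered
# event table. Unrecorded segments are kept in the timeline with
# recorded = FALSE so that stimulus indices used for habituation bookkeeping
# are unambiguous. All interstimulus intervals are onset-to-onset.

STIMULUS_KINDS <- c("light_on", "light_off", "light_flash", "dark_flash", "acoustic")
INTENSITY_LEVELS <- c("none", "low", "medium", "high")
PREPULSE_LEADS_MS <- c(50, 300)

#' Construct an assay block
#'
#' @param assay One of `"VMR"`, `"LF"`, `"DF"`, `"ASR"`.
#' @param frame_rate_fps Acquisition frame rate for the block (20 fps for the
#'   VMR assay, 500 fps for stimulus-response assays).
#' @param record_window_ms Post-stimulus recording span in ms (`NA` for the
#'   continuously recorded VMR block).
#' @param events Data frame of stimulus events with columns `onset_ms`,
#'   `kind`, `intensity`, `prepulse_intensity`, `prepulse_lead_ms`,
#'   `duration_ms`, `recorded`, `block_id`, `stimulus_index`.
#' @return A list of class `assay_block`.
#' @export
assay_block <- function(assay, frame_rate_fps, record_window_ms, events) {
  assay <- match.arg(assay, c("VMR", "LF", "DF", "ASR"))
  stopifnot(is.numeric(frame_rate_fps), frame_rate_fps > 0)
  validate_events(events)
  block <- list(
    assay = assay,
    frame_rate_fps = frame_rate_fps,
    record_window_ms = record_window_ms,
    events = events
  )
  class(block) <- "assay_block"
  block
}

validate_events <- function(events) {
  req <- c(
    "onset_ms", "kind", "intensity", "prepulse_intensity",
    "prepulse_lead_ms", "duration_ms", "recorded", "block_id",
    "stimulus_index"
  )
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("event table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(events$onset_ms < 0)) stop("event onsets must be >= 0")
  if (is.unsorted(events$onset_ms, strictly = TRUE)) {
    stop("event onsets must be strictly increasing within a block")
  }
  if (!all(events$kind %in% STIMULUS_KINDS)) stop("unknown stimulus kind")
  if (!all(events$intensity %in% INTENSITY_LEVELS)) stop("unknown intensity level")
  has_pp <- !is.na(events$prepulse_intensity)
  if (any(has_pp & events$kind != "acoustic")) {
    stop("prepulse is only defined for acoustic events")
  }
  if (!all(events$prepulse_intensity[has_pp] %in% c("low", "medium"))) {
    stop("prepulse intensity must be low or medium")
  }
  if (!all(events$prepulse_lead_ms[has_pp] %in% PREPULSE_LEADS_MS)) {
    stop("prepulse lead must be 50 or 300 ms")
  }
  if (any(has_pp != !is.na(events$prepulse_lead_ms))) {
    stop("prepulse intensity and lead must be set together")
  }
  invisible(events)
}

event_frame <- function(onset_ms, kind, intensity = "none",
                        prepulse_intensity = NA_character_,
                        prepulse_lead_ms = NA_real_,
                        duration_ms, recorded, block_id, stimulus_index) {
  data.frame(
    onset_ms = as.numeric(onset_ms),
    kind = kind,
    intensity = intensity,
    prepulse_intensity = prepulse_intensity,
    prepulse_lead_ms = as.numeric(prepulse_lead_ms),
    duration_ms = as.numeric(duration_ms),
    recorded = recorded,
    block_id = block_id,
    stimulus_index = as.integer(stimulus_index),
    stringsAsFactors = FALSE
  )
}

#' Build the default two-hour behavioral paradigm
#'
#' Encodes the published four-block paradigm exactly:
#' \itemize{
#'   \item VMR: 10 min lights-off (unrecorded), 8 min lights-on and 8 min
#'     lights-off, both recorded continuously at 20 fps.
#'   \item LF: 15 white-light flashes of 500 ms, 30 s ISI; 500 ms recorded
#'     post-stimulus at 500 fps.
#'   \item DF: 5 min lights-on adaptation (unrecorded), then five blocks of
#'     14 dark flashes of 1 s each (30 s ISI in block 1, 10 s thereafter);
#'     blocks 1, 3 and 5 recorded, 1 s post-stimulus at 500 fps.
#'   \item ASR: 10 low-intensity and 10 medium-intensity acoustic stimuli at
#'     20 s ISI, 10 repetitions of the PPI1-PPI2-PPI3-PPI4-High pattern at
#'     20 s ISI (PPI1: low prepulse 50 ms before a high pulse; PPI2: low,
#'     300 ms; PPI3: medium, 50 ms; PPI4: medium, 300 ms), then a
#'     habituation train of 30 high-intensity stimuli at 1 s ISI; 200 ms
#'     recorded post-stimulus at 500 fps.
#' }
#'
#' All ISIs are onset-to-onset. Onsets are in ms from the start of the block.
#'
#' @return A `protocol` object (ordered list of [assay_block()]s).
#' @seealso [events_of()], [write_protocol()]
#' @export
#' @examples
#' p <- build_default_protocol()
#' nrow(events_of(p, "LF"))  # 15 light flashes
build_default_protocol <- function() {
  vmr <- event_frame(
    onset_ms = c(0, 600000, 1080000),
    kind = c("light_off", "light_on", "light_off"),
    duration_ms = c(600000, 480000, 480000),
    recorded = c(FALSE, TRUE, TRUE),
    block_id = "VMR",
    stimulus_index = 1:3
  )

  lf <- event_frame(
    onset_ms = seq(0, by = 30000, length.out = 15),
    kind = "light_flash",
    duration_ms = 500,
    recorded = TRUE,
    block_id = "LF",
    stimulus_index = 1:15
  )

  # DF: 5 min lights-on, then five 14-flash blocks. Block 1 runs at 30 s ISI;
  # blocks 2-5 at 10 s ISI, with the inter-block gap equal to the following
  # block's ISI. Blocks 1, 3 and 5 are recorded.
  df_adapt <- event_frame(
    onset_ms = 0, kind = "light_on", duration_ms = 300000,
    recorded = FALSE, block_id = "DF_adapt", stimulus_index = NA_integer_
  )
  df_onsets <- 300000 + c(
    seq(0, by = 30000, length.out = 14),
    13 * 30000 + seq(10000, by = 10000, length.out = 14 * 4)
  )
  df_block_no <- rep(1:5, each = 14)
  df <- event_frame(
    onset_ms = df_onsets,
    kind = "dark_flash",
    duration_ms = 1000,
    recorded = df_block_no %in% c(1, 3, 5),
    block_id = paste0("DF", df_block_no),
    stimulus_index = 1:70
  )
  df <- rbind(df_adapt, df)

  ppi_pattern <- data.frame(
    block_id = c("ASR_ppi1", "ASR_ppi2", "ASR_ppi3", "ASR_ppi4", "ASR_high20"),
    prepulse_intensity = c("low", "low", "medium", "medium", NA),
    prepulse_lead_ms = c(50, 300, 50, 300, NA),
    stringsAsFactors = FALSE
  )
  asr <- rbind(
    event_frame(
      onset_ms = seq(0, by = 20000, length.out = 10),
      kind = "acoustic", intensity = "low", duration_ms = 2,
      recorded = TRUE, block_id = "ASR_low", stimulus_index = 1:10
    ),
    event_frame(
      onset_ms = 200000 + seq(0, by = 20000, length.out = 10),
      kind = "acoustic", intensity = "medium", duration_ms = 2,
      recorded = TRUE, block_id = "ASR_med", stimulus_index = 11:20
    ),
    event_frame(
      onset_ms = 400000 + seq(0, by = 20000, length.out = 50),
      kind = "acoustic", intensity = "high",
      prepulse_intensity = rep(ppi_pattern$prepulse_intensity, 10),
      prepulse_lead_ms = rep(ppi_pattern$prepulse_lead_ms, 10),
      duration_ms = 2,
      recorded = TRUE, block_id = rep(ppi_pattern$block_id, 10),
      stimulus_index = 21:70
    ),
    event_frame(
      onset_ms = 1400000 + seq(0, by = 1000, length.out = 30),
      kind = "acoustic", intensity = "high", duration_ms = 2,
      recorded = TRUE, block_id = "ASR_hab", stimulus_index = 71:100
    )
  )

  protocol(list(
    assay_block("VMR", 20, NA_real_, vmr),
    assay_block("LF", 500, 500, lf),
    assay_block("DF", 500, 1000, df),
    assay_block("ASR", 500, 200, asr)
  ))
}

#' Construct a protocol from assay blocks
#'
#' @param blocks List of [assay_block()]s in paradigm order
#'   (VMR, LF, DF, ASR for the published paradigm).
#' @return A `protocol` object.
#' @export
protocol <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  for (b in blocks) {
    if (!inherits(b, "assay_block")) stop("all blocks must be assay_block objects")
  }
  assays <- vapply(blocks, `[[`, character(1), "assay")
  if (anyDuplicated(assays)) stop("duplicate assay blocks")
  names(blocks) <- assays
  structure(list(blocks = blocks), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol> ", length(x$blocks), " blocks\n", sep = "")
  for (b in x$blocks) {
    cat(
      sprintf(
        "  %-3s %4g fps, %3d events (%d recorded), window %s ms\n",
        b$assay, b$frame_rate_fps, nrow(b$events), sum(b$events$recorded),
        ifelse(is.na(b$record_window_ms), "-", b$record_window_ms)
      )
    )
  }
  invisible(x)
}

#' Query stimulus events of an assay block
#'
#' @param protocol A `protocol`.
#' @param assay Assay label (`"VMR"`, `"LF"`, `"DF"`, `"ASR"`).
#' @param filter Optional predicate: a function taking the event data frame
#'   and returning a logical vector over rows.
#' @return The matching events, in protocol order.
#' @export
#' @examples
#' p <- build_default_protocol()
#' nrow(events_of(p, "DF", function(e) e$recorded))  # 42
events_of <- function(protocol, assay, filter = NULL) {
  stopifnot(inherits(protocol, "protocol"))
  if (!assay %in% names(protocol$blocks)) {
    stop("unknown assay label: ", assay)
  }
  ev <- protocol$blocks[[assay]]$events
  if (!is.null(filter)) {
    keep <- filter(ev)
    if (!is.logical(keep) || length(keep) != nrow(ev)) {
      stop("filter must return one logical per event")
    }
    ev <- ev[which(keep), , drop = FALSE]
  }
  ev
}

#' Serialize a protocol to JSON
#'
#' The schema is `{blocks: [{assay, frame_rate_fps, record_window_ms,
#' events: [...]}]}`; [read_protocol()] restores an identical object.
#'
#' @param protocol A `protocol`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol"))
  blocks <- lapply(protocol$blocks, function(b) {
    list(
      assay = b$assay,
      frame_rate_fps = b$frame_rate_fps,
      record_window_ms = b$record_window_ms,
      events = b$events
    )
  })
  jsonlite::write_json(
    list(blocks = unname(blocks)),
    path,
    dataframe = "columns", na = "null", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a protocol from JSON
#'
#' @param path File written by [write_protocol()].
#' @return A `protocol` object.
#' @export
read_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  col <- function(x, mode) {
    vapply(x, function(v) {
      if (is.null(v)) {
        switch(mode, c = NA_character_, n = NA_real_, i = NA_integer_, l = NA)
      } else {
        switch(mode,
          c = as.character(v), n = as.numeric(v),
          i = as.integer(v), l = as.logical(v)
        )
      }
    }, switch(mode, c = character(1), n = numeric(1), i = integer(1), l = logical(1)))
  }
  blocks <- lapply(raw$blocks, function(b) {
    e <- b$events
    ev <- data.frame(
      onset_ms = col(e$onset_ms, "n"),
      kind = col(e$kind, "c"),
      intensity = col(e$intensity, "c"),
      prepulse_intensity = col(e$prepulse_intensity, "c"),
      prepulse_lead_ms = col(e$prepulse_lead_ms, "n"),
      duration_ms = col(e$duration_ms, "n"),
      recorded = col(e$recorded, "l"),
      block_id = col(e$block_id, "c"),
      stimulus_index = col(e$stimulus_index, "i"),
      stringsAsFactors = FALSE
    )
    assay_block(
      assay = b$assay,
      frame_rate_fps = as.numeric(b$frame_rate_fps),
      record_window_ms = if (is.null(b$record_window_ms)) NA_real_ else as.numeric(b$record_window_ms),
      events = ev
    )
  })
  protocol(blocks)
}

# Start/duration of the two recorded VMR phases, in block-relative ms.
vmr_phases <- function(protocol) {
  ev <- events_of(protocol, "VMR", function(e) e$recorded)
  if (nrow(ev) != 2) stop("expected two recorded VMR phases")
  list(
    light = list(start = ev$onset_ms[1], duration = ev$duration_ms[1]),
    dark = list(start = ev$onset_ms[2], duration = ev$duration_ms[2])
  )
}
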