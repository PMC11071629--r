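#' Write a session bundle to disk
#'
#' Serializes an `ephys_session` as a directory of plain-text files:
#' `events.tsv` (one row per trial), `spikes.tsv`, `eye.tsv`, `meta.json`,
#' and `objects.tsv` for fixation sessions. Times are ms from session
#' start; missing events are empty fields.
#'
#' @param session An `ephys_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- session$trials
  ev$action <- as.character(ev$action)
  write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE, na = "")
  spikes <- data.frame(neuron_id = session$neuron_id,
                       t_ms = if (is.null(session$spikes)) numeric(0) else
                         session$spikes)
  write.table(spikes, file.path(dir, "spikes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(session$eye)) {
    write.table(session$eye, file.path(dir, "eye.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (!is.null(session$objects)) {
    write.table(session$objects, file.path(dir, "objects.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  meta <- list(monkey_id = session$monkey_id, neuron_id = session$neuron_id,
               region = session$region, hemisphere = session$hemisphere,
               task = session$task, seed = session$seed,
               archetype = session$archetype,
               config = unclass(session$config))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a session bundle from disk
#'
#' @param dir Directory written by [write_session()].
#' @return An `ephys_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  trials <- read.delim(file.path(dir, "events.tsv"),
                       stringsAsFactors = FALSE)
  trials$action <- factor(trials$action,
                          levels = c("Accept", "Return", "Stay", "Other",
                                     "FixBreak"))
  trials$value <- as.character(trials$value)
  sp <- read.delim(file.path(dir, "spikes.tsv"), stringsAsFactors = FALSE)
  session <- list(monkey_id = meta$monkey_id, neuron_id = meta$neuron_id,
                  region = meta$region, hemisphere = meta$hemisphere,
                  task = meta$task, seed = meta$seed,
                  config = do.call(task_config, meta$config),
                  trials = trials,
                  spikes = if (nrow(sp)) sp$t_ms else numeric(0),
                  eye = NULL)
  if (!is.null(meta$archetype)) session$archetype <- meta$archetype
  eye_path <- file.path(dir, "eye.tsv")
  if (file.exists(eye_path)) {
    eye <- read.delim(eye_path, stringsAsFactors = FALSE)
    class(eye) <- c("eye_trace", "data.frame")
    session$eye <- eye
  }
  obj_path <- file.path(dir, "objects.tsv")
  if (file.exists(obj_path)) {
    session$objects <- read.delim(obj_path, stringsAsFactors = FALSE)
  }
  class(session) <- "ephys_session"
  session
}

#' @export
print.ephys_session <- function(x, ...) {
  cat(sprintf("<ephys_session> %s task, monkey %s, neuron %s (%s, %s)\n",
              x$task, x$monkey_id, x$neuron_id, x$region, x$hemisphere))
  cat(sprintf("  %d trials, %d spikes, eye trace: %s\n",
              nrow(x$trials),
              length(x$spikes),
              if (is.null(x$eye)) "absent" else
                sprintf("%d samples", nrow(x$eye))))
  invisible(x)
}
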