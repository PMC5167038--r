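#' Write a study bundle to a directory of TSV files
#'
#' Serialises a simulated scenario (or an existing `study_bundle`) in the
#' plain-text dialect [read_bundle()] reads: one `traps_<site>.tsv` per site
#' (`trap_id`, `x`, `y` in metres), a `captures.tsv` (`session`,
#' `animal_id`, `occasion`, `trap_id`, plus `sex` where present), a
#' `sessions.tsv` index (so sessions with zero captures round-trip) and a
#' `mast_years.txt` calendar. Sessions are labelled `site-year-month`.
#'
#' @param x output of [mast_cycle_scenario()] or a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  if (inherits(x, "study_bundle")) {
    bundle <- x
  } else {                                   # scenario output
    stopifnot(is.list(x), !is.null(x$sessions), !is.null(x$truth))
    sites <- unique(x$truth$site)
    bundle <- study_bundle(
      traps = stats::setNames(rep(list(x$traps), length(sites)), sites),
      sessions = x$sessions,
      index = data.frame(key = names(x$sessions),
                         session = sprintf("%s-%d-%02d", x$truth$site,
                                           x$truth$year, x$truth$month),
                         site = x$truth$site, year = x$truth$year,
                         month = x$truth$month, sex = x$truth$sex,
                         n_occasions = x$config$n_occasions,
                         stringsAsFactors = FALSE),
      mast_years = x$config$mast_years)
  }
  for (site in names(bundle$traps))
    wr(bundle$traps[[site]], paste0("traps_", site, ".tsv"))
  caps <- do.call(rbind, lapply(seq_len(nrow(bundle$index)), function(i) {
    rec <- bundle$sessions[[bundle$index$key[i]]]$records
    if (nrow(rec) == 0) return(NULL)
    cbind(session = bundle$index$session[i], rec,
          if (!is.na(bundle$index$sex[i])) data.frame(sex = bundle$index$sex[i]))
  }))
  if (is.null(caps))
    caps <- data.frame(session = character(), animal_id = character(),
                       occasion = integer(), trap_id = character())
  wr(caps, "captures.tsv")
  wr(bundle$index[setdiff(names(bundle$index), "key")], "sessions.tsv")
  writeLines(as.character(bundle$mast_years), file.path(dir, "mast_years.txt"))
  invisible(dir)
}

study_bundle <- function(traps, sessions, index, mast_years,
                         seed_quadrats = NULL) {
  structure(list(traps = traps, sessions = sessions, index = index,
                 mast_years = mast_years, seed_quadrats = seed_quadrats),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("Study bundle: %d sites, %d sessions, mast autumns %s\n",
              length(x$traps), nrow(x$index),
              paste(x$mast_years, collapse = ", ")))
  invisible(x)
}

#' Read a study bundle from a directory of TSV files
#'
#' Reads and validates the dialect written by [write_bundle()]. Captures
#' referencing unknown traps, malformed occasion indices, and duplicated
#' `(session, sex, animal, occasion)` rows are errors reported with file
#' line numbers. If `captures.tsv` carries a `check_time` column, only
#' `"morning"` rows are kept by default (evening captures are a negligible
#' fraction of a morning-checked design and are excluded from analysis).
#'
#' @param dir directory containing the bundle.
#' @param n_occasions occasions per session when `sessions.tsv` is absent.
#' @param morning_only drop non-morning rows of a `check_time` column?
#' @return A `study_bundle`: per-site [trap_array()]s, a named list of
#'   [capture_session()]s keyed `site-year-month[-sex]`, the session index
#'   and the mast calendar.
#' @export
read_bundle <- function(dir, n_occasions = 5, morning_only = TRUE) {
  stopifnot(dir.exists(dir))
  tf <- list.files(dir, "^traps_.*\\.tsv$", full.names = TRUE)
  if (!length(tf)) stop("no traps_<site>.tsv files in ", dir)
  traps <- lapply(tf, function(f) {
    d <- utils::read.delim(f, stringsAsFactors = FALSE)
    trap_array(d$trap_id, d$x, d$y)
  })
  names(traps) <- sub("^traps_(.*)\\.tsv$", "\\1", basename(tf))

  caps <- utils::read.delim(file.path(dir, "captures.tsv"),
                            stringsAsFactors = FALSE)
  caps$line <- seq_len(nrow(caps)) + 1L          # header is line 1
  if (morning_only && "check_time" %in% names(caps))
    caps <- caps[caps$check_time == "morning", , drop = FALSE]
  if (nrow(caps)) {
    occ <- suppressWarnings(as.numeric(caps$occasion))
    bad <- is.na(occ) | occ != floor(occ) | occ < 1
    if (any(bad))
      stop("malformed occasion at line(s) ",
           paste(caps$line[bad], collapse = ", "))
    caps$occasion <- as.integer(occ)
  }
  has_sex <- "sex" %in% names(caps)
  keycols <- c("session", if (has_sex) "sex", "animal_id", "occasion")
  dup <- duplicated(caps[keycols])
  if (any(dup))
    stop("duplicate (animal, occasion) rows at line(s) ",
         paste(caps$line[dup], collapse = ", "))

  sess_file <- file.path(dir, "sessions.tsv")
  if (file.exists(sess_file)) {
    index <- utils::read.delim(sess_file, stringsAsFactors = FALSE)
  } else {
    u <- unique(caps[c("session", if (has_sex) "sex")])
    parts <- strsplit(u$session, "-")
    index <- data.frame(session = u$session,
                        site = vapply(parts, function(p)
                          paste(p[seq_len(length(p) - 2)], collapse = "-"), ""),
                        year = as.integer(vapply(parts, function(p)
                          p[length(p) - 1], "")),
                        month = as.integer(vapply(parts, function(p)
                          p[length(p)], "")),
                        sex = if (has_sex) u$sex else NA_character_,
                        n_occasions = n_occasions, stringsAsFactors = FALSE)
  }
  if (!"sex" %in% names(index)) index$sex <- NA_character_
  index$key <- ifelse(is.na(index$sex), index$session,
                      paste(index$session, index$sex, sep = "-"))
  bad_site <- setdiff(index$site, names(traps))
  if (length(bad_site)) stop("sessions reference unknown site(s): ",
                             paste(bad_site, collapse = ", "))
  sessions <- lapply(seq_len(nrow(index)), function(i) {
    sel <- caps$session == index$session[i]
    if (has_sex && !is.na(index$sex[i])) sel <- sel & caps$sex == index$sex[i]
    rec <- caps[sel, c("animal_id", "occasion", "trap_id"), drop = FALSE]
    ti <- match(rec$trap_id, traps[[index$site[i]]]$trap_id)
    if (anyNA(ti))
      stop("unknown trap_id at line(s) ",
           paste(caps$line[sel][is.na(ti)], collapse = ", "))
    capture_session(index$session[i], index$n_occasions[i], rec)
  })
  names(sessions) <- index$key
  sq_file <- file.path(dir, "seed_quadrats.tsv")
  sq <- if (file.exists(sq_file))
    utils::read.delim(sq_file, stringsAsFactors = FALSE) else NULL
  my <- as.numeric(readLines(file.path(dir, "mast_years.txt")))
  study_bundle(traps, sessions, index, my, sq)
}

#' Trap-night accounting
#'
#' Total trapping effort: number of physical site-sessions times traps per
#' grid times nights per session. For a `study_bundle` the count of
#' site-sessions ignores any sex splitting of the capture data (both sexes
#' share the same trap-nights).
#'
#' @param x a `study_bundle`, or the number of site-sessions.
#' @param ... method arguments.
#' @return Total trap nights.
#' @examples
#' trap_nights(8 * 16, n_traps = 64, n_nights = 5)  # 40960
#' @export
trap_nights <- function(x, ...) UseMethod("trap_nights")

#' @rdname trap_nights
#' @param n_traps traps per grid.
#' @param n_nights nights (occasions) per session.
#' @export
trap_nights.default <- function(x, n_traps, n_nights, ...) {
  x * n_traps * n_nights
}

#' @rdname trap_nights
#' @export
trap_nights.study_bundle <- function(x, ...) {
  u <- unique(x$index[c("site", "year", "month")])
  sum(vapply(seq_len(nrow(u)), function(i) {
    key <- x$index$site == u$site[i] & x$index$year == u$year[i] &
      x$index$month == u$month[i]
    nrow(x$traps[[u$site[i]]]) * max(x$index$n_occasions[key])
  }, 0))
}

#' Run the full analysis pipeline on a study bundle
#'
#' For each sex: fits every candidate model structure to every site
#' independently (sites have separate parameters, so the study-wide model is
#' the sum of per-site fits), ranks the summed fits by AICc, expands the
#' best structure's per-session `(D, sigma)` estimates, then computes
#' overlap statistics and the two mixed models across sexes. All outputs are
#' TSV plus a line-oriented run log; any stage failure halts with a
#' stage-named error, preserving completed outputs.
#'
#' @param bundle a `study_bundle` from [read_bundle()] or [write_bundle()]'s
#'   input scenario.
#' @param out_dir output directory.
#' @param specs candidate [model_spec()] list (default [enumerate_models()]).
#' @param buffer,mask_spacing habitat-mask settings in metres.
#' @param seed integer seed recorded in the log (set before any simulation
#'   upstream; the pipeline itself is deterministic).
#' @return Invisibly, a list with the per-sex model tables, the space-use
#'   records, the overlap statistics and the two Wald Type II tables.
#' @export
run_pipeline <- function(bundle, out_dir, specs = enumerate_models(),
                         buffer = 100, mask_spacing = 10, seed = NULL) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("mastsecr pipeline run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logline("R %s, mastsecr %s", getRversion(),
          as.character(utils::packageVersion("mastsecr")))
  logline("seed: %s; buffer %g m; mask spacing %g m; %d candidate models",
          if (is.null(seed)) "none" else seed, buffer, mask_spacing,
          length(specs))
  wr <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))

  masks <- lapply(bundle$traps, build_mask, buffer = buffer,
                  spacing = mask_spacing)
  sexes <- unique(bundle$index$sex)
  sexes <- sexes[!is.na(sexes)]
  if (!length(sexes)) sexes <- NA_character_
  tables <- list(); all_rows <- list(); fit_rows <- list()
  for (sx in sexes) {
    idx <- if (is.na(sx)) bundle$index else bundle$index[bundle$index$sex == sx, ]
    agg <- stage("fit", lapply(specs, function(sp) {
      per_site <- lapply(split(idx, idx$site), function(si) {
        tryCatch(fit_secr(bundle$sessions[si$key],
                          bundle$traps[[si$site[1]]], masks[[si$site[1]]],
                          spec = sp),
                 error = function(e) {
                   logline("  [%s] site %s, model '%s' failed: %s", sx,
                           si$site[1], spec_label(sp), conditionMessage(e))
                   NULL
                 })
      })
      ok <- !vapply(per_site, is.null, TRUE)
      list(spec = sp,
           loglik = sum(vapply(per_site[ok], `[[`, 0, "loglik")),
           K_params = sum(vapply(per_site[ok], `[[`, 0L, "K_params")),
           n_individuals = sum(vapply(per_site[ok], `[[`, 0L, "n_individuals")),
           converged = all(ok) && all(vapply(per_site[ok], `[[`, TRUE,
                                             "converged")),
           fits = per_site)
    }))
    tab <- stage("select", model_table(agg))
    tables[[as.character(sx)]] <- tab
    wr(tab, sprintf("model_table_%s.tsv", if (is.na(sx)) "all" else sx))
    best <- agg[[match(tab$model[1], vapply(agg, function(a)
      spec_label(a$spec), ""))]]
    logline("[%s] best model: %s (AICc weight %.3f)", sx, tab$model[1],
            tab$weight[1])
    for (site in names(best$fits)) {
      f <- best$fits[[site]]
      if (is.null(f)) next
      se <- session_estimates(f)
      meta <- idx[match(se$session_id, idx$session), ]
      all_rows[[paste(sx, site)]] <-
        data.frame(site = site, year = meta$year, month = meta$month,
                   sex = sx, D_hat = se$D, sigma_hat = se$sigma,
                   converged = f$converged, stringsAsFactors = FALSE)
      fit_rows[[paste(sx, site)]] <- cbind(sex = sx, site = site,
                                           f$estimates)
    }
  }
  fits_df <- do.call(rbind, fit_rows)
  wr(fits_df, "fits.tsv")
  records <- stage("records", assemble_records(do.call(rbind, all_rows),
                                               bundle$mast_years))
  ov <- stage("overlap", overlap_stats(records))
  wr(ov$per_session, "overlap.tsv")
  wr(ov$phase_k, "overlap_phase_k.tsv")
  wr(ov$phase_S95, "overlap_phase_S95.tsv")
  glmm_out <- list()
  for (fid in c("density_model", "sigma_model")) {
    fit <- stage(fid, fit_lmm(records, fid))
    w <- wald_type2(fit)
    glmm_out[[fid]] <- w
    wr(w, sprintf("glmm_%s.tsv", sub("_model", "", fid)))
  }
  logline("records: %d; done", nrow(records))
  invisible(list(model_tables = tables, records = records, overlap = ov,
                 glmm = glmm_out))
}
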