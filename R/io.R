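#' Read a TPS landmark file
#'
#' Parses the community-standard TPS dialect: each record starts with
#' `LM=k`, followed by k lines of whitespace-separated x/y coordinates and
#' optional `IMAGE=`, `ID=` and `SCALE=` lines. `SCALE`, when present,
#' multiplies the coordinates of its record.
#'
#' Coordinates are kept in a mathematical frame (x right, y up). Files
#' written by image tools that count y downwards can be flipped on read
#' with `flip_y = TRUE`; a silent reflection would flip every sex-difference
#' vector downstream, so the switch is explicit.
#'
#' @param path Path to a TPS file.
#' @param flip_y Negate the y coordinate on read (image-convention files).
#' @return A tibble with one row per record: `id`, `image`, `scale` and a
#'   list-column `points` of k x 2 coordinate matrices.
#' @export
read_tps <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  recs <- list()
  i <- 1L
  n_total <- length(lines)
  while (i <= n_total) {
    ln <- lines[[i]]
    if (ln == "") {
      i <- i + 1L
      next
    }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      abort(paste0("line ", i, ": expected 'LM=' record header, got: ", ln))
    }
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 0) abort(paste0("line ", i, ": malformed LM count"))
    rec_line <- i
    i <- i + 1L
    pts <- matrix(NA_real_, nrow = k, ncol = 2)
    for (j in seq_len(k)) {
      if (i > n_total || grepl("^(LM|IMAGE|ID|SCALE)\\s*=", lines[[i]], ignore.case = TRUE)) {
        abort(paste0(
          "record starting at line ", rec_line, ": LM=", k,
          " but only ", j - 1L, " coordinate line(s) present"
        ))
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[[i]], "\\s+")[[1]]))
      if (length(xy) != 2 || anyNA(xy)) {
        abort(paste0("line ", i, ": non-numeric or malformed coordinate pair"))
      }
      pts[j, ] <- xy
      i <- i + 1L
    }
    image <- NA_character_; id <- NA_character_; scale <- NA_real_
    while (i <= n_total && !grepl("^LM\\s*=", lines[[i]], ignore.case = TRUE)) {
      ln2 <- lines[[i]]
      if (grepl("^IMAGE\\s*=", ln2, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", ln2, ignore.case = TRUE)
      } else if (grepl("^ID\\s*=", ln2, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln2, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln2, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=\\s*", "", ln2, ignore.case = TRUE)))
        if (is.na(scale)) abort(paste0("line ", i, ": non-numeric SCALE"))
      } else if (ln2 != "") {
        abort(paste0("line ", i, ": unexpected extra coordinate line (LM count too small?)"))
      }
      i <- i + 1L
    }
    if (!is.na(scale)) pts <- pts * scale
    if (flip_y) pts[, 2] <- -pts[, 2]
    if (any(!is.finite(pts))) {
      abort(paste0("record starting at line ", rec_line, ": non-finite coordinates"))
    }
    recs[[length(recs) + 1L]] <- list(id = id, image = image, scale = scale, points = pts)
  }
  if (!length(recs)) {
    return(tibble::tibble(
      id = character(), image = character(),
      scale = numeric(), points = list()
    ))
  }
  ids <- vapply(recs, function(r) r$id, character(1))
  imgs <- vapply(recs, function(r) r$image, character(1))
  miss <- is.na(ids)
  ids[miss] <- ifelse(!is.na(imgs[miss]), imgs[miss],
                      paste0("specimen_", which(miss)))
  tibble::tibble(
    id = ids,
    image = imgs,
    scale = vapply(recs, function(r) r$scale, numeric(1)),
    points = lapply(recs, function(r) r$points)
  )
}

#' @rdname read_tps
#' @param configs A tibble as returned by [read_tps()] (columns `id`,
#'   `points`, optionally `image`). Coordinates are written at full
#'   precision; `SCALE` is not re-applied.
#' @param digits Decimal places written (default 6, the usual TPS precision).
#' @export
write_tps <- function(configs, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(configs))) {
    pts <- configs$points[[i]]
    writeLines(paste0("LM=", nrow(pts)), con)
    writeLines(
      paste(formatC(pts[, 1], format = "f", digits = digits),
            formatC(pts[, 2], format = "f", digits = digits)),
      con
    )
    img <- if ("image" %in% names(configs)) configs$image[[i]] else NA
    if (!is.na(img)) writeLines(paste0("IMAGE=", img), con)
    writeLines(paste0("ID=", configs$id[[i]]), con)
  }
  invisible(path)
}

#' Read a per-individual metadata table
#'
#' Expects a delimited table with at least `id`, `sex` and `population`
#' columns; `height` (cm), `weight` (kg), `focal_length` (mm) and
#' `attractiveness` are optional. Blank cells become missing values. Sex
#' tokens are normalized to `female`/`male`.
#'
#' @param path Path to the table.
#' @param delim Field delimiter (default ",").
#' @return A tibble of typed metadata records.
#' @export
read_metadata <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  names(raw) <- tolower(names(raw))
  need <- c("id", "sex", "population")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("metadata is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  raw$id <- as.character(raw$id)
  dup <- raw$id[duplicated(raw$id)]
  if (length(dup)) {
    abort(paste0("duplicate id(s) in metadata: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(raw$sex)) || any(is.na(raw$population))) {
    bad <- raw$id[is.na(raw$sex) | is.na(raw$population)]
    abort(paste0("sex/population missing for id(s): ", paste(bad, collapse = ", ")))
  }
  raw$sex <- tryCatch(check_sex(raw$sex), error = function(e) {
    s <- tolower(trimws(as.character(raw$sex)))
    bad <- !(s %in% c("f", "female", "w", "woman", "m", "male", "man"))
    abort(paste0(
      "unknown sex token(s) for id(s): ",
      paste(raw$id[bad], collapse = ", ")
    ))
  })
  raw$population <- as.character(raw$population)
  for (col in c("height", "weight", "focal_length", "attractiveness")) {
    if (col %in% names(raw)) raw[[col]] <- as.numeric(raw[[col]])
  }
  for (col in c("height", "weight", "focal_length")) {
    if (col %in% names(raw) && any(raw[[col]] <= 0, na.rm = TRUE)) {
      abort(paste0("non-positive ", col, " for id(s): ",
                   paste(raw$id[which(raw[[col]] <= 0)], collapse = ", ")))
    }
  }
  tibble::as_tibble(raw)
}

#' Report the overlap between landmark configurations and metadata
#'
#' @param configs Tibble with an `id` column (e.g. from [read_tps()]).
#' @param metadata Tibble with an `id` column (e.g. from [read_metadata()]).
#' @return A list with `matched`, `unmatched_configs`, `unmatched_metadata`.
#' @export
join_report <- function(configs, metadata) {
  a <- unique(as.character(configs$id))
  b <- unique(as.character(metadata$id))
  list(
    matched = sort(intersect(a, b)),
    unmatched_configs = sort(setdiff(a, b)),
    unmatched_metadata = sort(setdiff(b, a))
  )
}

#' Assemble a validated landmark dataset
#'
#' Joins landmark configurations to metadata under a template, checking
#' landmark counts and id coverage. The result is ordered by id, so the
#' assembled dataset is invariant to input file order.
#'
#' @param configs Tibble from [read_tps()] (columns `id`, `points`).
#' @param metadata Tibble from [read_metadata()].
#' @param template A [landmark_template()].
#' @param quiet Suppress the per-population x sex count message.
#' @return A tibble of class `face_dataset`: metadata columns plus flat
#'   coordinate columns `x1..yk`; the template is attached as an attribute.
#' @export
assemble_dataset <- function(configs, metadata, template, quiet = FALSE) {
  k <- template$n_landmarks
  ks <- vapply(configs$points, nrow, integer(1))
  if (any(ks != k)) {
    abort(paste0(
      "landmark count != ", k, " for id(s): ",
      paste(configs$id[ks != k], collapse = ", ")
    ))
  }
  rep_ids <- join_report(configs, metadata)
  if (length(rep_ids$unmatched_configs)) {
    abort(paste0(
      "configurations without metadata: ",
      paste(rep_ids$unmatched_configs, collapse = ", ")
    ))
  }
  coords <- shapes_tibble(
    do.call(rbind, lapply(configs$points, as_flat)),
    id = configs$id
  )
  out <- dplyr::inner_join(metadata, coords, by = "id")
  out <- dplyr::arrange(out, .data$id)
  if (!quiet) {
    counts <- table(out$population, out$sex)
    message(
      "assembled ", nrow(out), " specimens (", k, " landmarks); ",
      "population x sex counts: ",
      paste(apply(as.data.frame(counts), 1, function(r) {
        paste0(r[1], "/", r[2], "=", r[3])
      }), collapse = ", ")
    )
  }
  attr(out, "template") <- template
  class(out) <- c("face_dataset", class(out))
  out
}
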