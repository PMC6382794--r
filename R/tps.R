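#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect written by common 2D digitizers: records start with
#' `LM=k`, followed by k lines of two whitespace-separated reals, then optional
#' `IMAGE=`, `ID=` and `SCALE=` lines. When `SCALE=` is present the
#' coordinates are multiplied by it, yielding coordinates in physical units.
#' Coordinates are y-up Cartesian; no image-axis flip is applied.
#'
#' Specimen metadata can be encoded in the record ID with the convention
#' `<specimen>_<L|R|N>_<img#>_<dig#>` (side, imaging replicate, digitization
#' replicate); trailing fields may be omitted and default to side `"none"`,
#' replicate 1. IDs that do not match the convention are kept verbatim as the
#' specimen ID. Metadata can instead (or additionally) be joined later from a
#' classifier table.
#'
#' @param path Path to a TPS file.
#' @param scheme Optional [landmark_scheme]; when given, every record must
#'   have `scheme$k` landmarks.
#' @return A tibble with one row per configuration: columns `specimen`,
#'   `side` (`"left"`, `"right"` or `"none"`), `image_rep`, `digit_rep`, `id`
#'   (the verbatim TPS ID), and a list-column `coords` of k x 2 matrices.
#' @examples
#' tf <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=s1_L_1_1"), tf)
#' read_tps(tf)
#' @export
read_tps <- function(path, scheme = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(lines) > 0L && length(starts) == 0L) abort("no LM= records found")
  recs <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:(bounds[r + 1L] - 1L)]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L], ignore.case = TRUE)))
    if (is.na(k) || k < 1L) abort(sprintf("record %d: unreadable LM= count", r))
    coord_lines <- block[-1L][!grepl("=", block[-1L], fixed = TRUE)]
    if (length(coord_lines) != k) {
      abort(sprintf("record %d: LM=%d declared but %d coordinate lines found",
                    r, k, length(coord_lines)))
    }
    xy <- do.call(rbind, lapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1L]]))
      if (length(v) != 2L || any(is.na(v))) {
        abort(sprintf("record %d: malformed coordinate line '%s'", r, l))
      }
      v
    }))
    meta <- block[-1L][grepl("=", block[-1L], fixed = TRUE)]
    get_field <- function(key) {
      m <- grep(paste0("^", key, "\\s*="), meta, ignore.case = TRUE, value = TRUE)
      if (length(m) == 0L) return(NA_character_)
      sub(paste0("^", key, "\\s*=\\s*"), "", m[1L], ignore.case = TRUE)
    }
    scale <- suppressWarnings(as.numeric(get_field("SCALE")))
    if (!is.na(scale)) xy <- xy * scale
    if (!is.null(scheme) && k != scheme$k) {
      abort(sprintf("record %d has %d landmarks but scheme '%s' expects %d",
                    r, k, scheme$name, scheme$k))
    }
    recs[[r]] <- list(id = get_field("ID"), image = get_field("IMAGE"), coords = xy)
  }
  ids <- vapply(recs, function(x) x$id %||% NA_character_, character(1))
  ids[is.na(ids)] <- paste0("config_", which(is.na(ids)))
  meta <- parse_config_ids(ids)
  tibble::tibble(
    specimen = meta$specimen, side = meta$side,
    image_rep = meta$image_rep, digit_rep = meta$digit_rep,
    id = ids,
    coords = lapply(recs, `[[`, "coords")
  )
}

# ID convention <specimen>_<L|R|N>_<img#>_<dig#>; missing fields default.
parse_config_ids <- function(ids) {
  n <- length(ids)
  specimen <- ids
  side <- rep("none", n)
  image_rep <- rep(1L, n)
  digit_rep <- rep(1L, n)
  m <- regmatches(ids, regexec("^(.*)_([LRN])(?:_([0-9]+))?(?:_([0-9]+))?$", ids))
  for (i in seq_len(n)) {
    g <- m[[i]]
    if (length(g) == 0L) next
    specimen[i] <- g[2L]
    side[i] <- switch(g[3L], L = "left", R = "right", N = "none")
    if (nzchar(g[4L])) image_rep[i] <- as.integer(g[4L])
    if (nzchar(g[5L])) digit_rep[i] <- as.integer(g[5L])
  }
  list(specimen = specimen, side = side, image_rep = image_rep, digit_rep = digit_rep)
}

format_config_id <- function(specimen, side, image_rep, digit_rep) {
  sprintf("%s_%s_%d_%d", specimen,
          c(left = "L", right = "R", none = "N")[side],
          as.integer(image_rep), as.integer(digit_rep))
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: writes one `LM=` record per row, with the ID
#' encoding specimen, side and replicate per the package's naming convention.
#' Round-tripping preserves coordinates to the printed precision (10
#' significant digits).
#'
#' @param configs Tibble as returned by [read_tps()] or [simulate_dataset()]
#'   (columns `specimen`, `side`, `image_rep`, `digit_rep`, `coords`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  ks <- vapply(configs$coords, nrow, integer(1))
  if (length(ks) > 0L && length(unique(ks)) != 1L) {
    abort("all configurations must share one scheme (equal landmark counts)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(configs))) {
    xy <- configs$coords[[i]]
    id <- if ("id" %in% names(configs) && !is.na(configs$id[i])) {
      configs$id[i]
    } else {
      format_config_id(configs$specimen[i], configs$side[i],
                       configs$image_rep[i], configs$digit_rep[i])
    }
    writeLines(c(sprintf("LM=%d", nrow(xy)),
                 sprintf("%.10g %.10g", xy[, 1L], xy[, 2L]),
                 sprintf("ID=%s", id)), con)
  }
  invisible(path)
}
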