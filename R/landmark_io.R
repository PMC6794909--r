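# Reading, validating, subsetting and writing landmark datasets.

#' The sixteen major equid limb bones
#'
#' Canonical bone identifiers used throughout the package: the pectoral and
#' pelvic girdles, the long bones, the metapodials, the tarsal bones and the
#' three phalanges of each limb.
#'
#' @return Character vector of 16 bone identifiers.
#' @export
equid_bones <- function() {
  c("scapula", "humerus", "radio_ulna", "metacarpal",
    "phalanx_ant_prox", "phalanx_ant_mid", "phalanx_ant_dist",
    "coxal", "femur", "tibia", "talus", "calcaneus", "metatarsal",
    "phalanx_post_prox", "phalanx_post_mid", "phalanx_post_dist")
}

#' Short plotting abbreviations for the equid limb bones
#' @return Named character vector mapping bone identifier to abbreviation.
#' @export
bone_abbreviations <- function() {
  c(scapula = "S", humerus = "H", radio_ulna = "R", metacarpal = "MC",
    phalanx_ant_prox = "PA1", phalanx_ant_mid = "PA2", phalanx_ant_dist = "PA3",
    coxal = "C", femur = "F", tibia = "T", talus = "TA", calcaneus = "CA",
    metatarsal = "MT", phalanx_post_prox = "PP1", phalanx_post_mid = "PP2",
    phalanx_post_dist = "PP3")
}

#' Create a single landmark configuration
#'
#' One bone of one specimen: an ordered set of 3D landmark coordinates.
#'
#' @param specimen_id Specimen identifier.
#' @param bone_id Bone identifier.
#' @param coords Numeric k x 3 matrix of landmark coordinates (k >= 4).
#' @param landmark_ids Optional landmark labels; defaults to `L01`, `L02`, ...
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, bone_id, coords,
                            landmark_ids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop_mh("coords must be a k x 3 matrix (got ", ncol(coords), " columns)")
  if (nrow(coords) < 4L)
    stop_mh("at least 4 landmarks are required for 3D analysis (got ",
            nrow(coords), ")")
  if (any(!is.finite(coords)))
    stop_mh("non-finite coordinate values in configuration ",
            specimen_id, "/", bone_id)
  if (is.null(landmark_ids))
    landmark_ids <- sprintf("L%02d", seq_len(nrow(coords)))
  if (length(landmark_ids) != nrow(coords))
    stop_mh("landmark_ids length does not match number of landmarks")
  dimnames(coords) <- list(landmark_ids, c("x", "y", "z"))
  structure(list(specimen_id = as.character(specimen_id),
                 bone_id = as.character(bone_id),
                 coords = coords),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration: specimen", x$specimen_id,
      "bone", x$bone_id, "-", nrow(x$coords), "landmarks\n")
  invisible(x)
}

#' Read landmark configurations from file
#'
#' Supports three dialects: TPS (`LM3=k` blocks with optional `ID=` lines),
#' NTS (rectangular matrix with a header line, optional row labels), and a
#' long-format CSV with columns `specimen_id, bone_id, landmark_id, x, y, z`.
#'
#' @param path File path.
#' @param format One of `"tps"`, `"nts"`, `"csv"`.
#' @param bone_id Bone identifier to attach to configurations read from TPS or
#'   NTS files (these formats do not carry one). Ignored for CSV.
#' @return List of [landmark_config] objects.
#' @export
read_landmarks <- function(path, format = c("tps", "nts", "csv"),
                           bone_id = "bone") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mh("file not found: ", path)
  switch(format,
         tps = read_landmarks_tps(path, bone_id),
         nts = read_landmarks_nts(path, bone_id),
         csv = read_landmarks_csv(path))
}

read_landmarks_tps <- function(path, bone_id) {
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  n_spec <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    m <- regmatches(line, regexec("^LM3=([0-9]+)$", line, ignore.case = TRUE))[[1]]
    if (length(m) == 0L)
      stop_mh("TPS parse error at line ", i, ": expected 'LM3=k', got '",
              line, "'")
    k <- as.integer(m[2])
    if (i + k > length(lines))
      stop_mh("TPS parse error: block starting at line ", i,
              " declares ", k, " landmarks but file ends early")
    coords <- matrix(NA_real_, k, 3L)
    for (j in seq_len(k)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]),
                                                   "[ \t]+")[[1]]))
      if (length(vals) != 3L || any(is.na(vals)))
        stop_mh("TPS parse error at line ", i + j,
                ": expected 3 numeric coordinates")
      coords[j, ] <- vals
    }
    i <- i + k + 1L
    n_spec <- n_spec + 1L
    id <- sprintf("specimen_%03d", n_spec)
    # optional ID= / IMAGE= lines follow the coordinate block
    while (i <= length(lines)) {
      line <- trimws(lines[i])
      if (grepl("^ID=", line, ignore.case = TRUE)) {
        id <- sub("^ID=", "", line, ignore.case = TRUE)
        i <- i + 1L
      } else if (grepl("^(IMAGE|SCALE)=", line, ignore.case = TRUE)) {
        i <- i + 1L
      } else break
    }
    configs[[length(configs) + 1L]] <- landmark_config(id, bone_id, coords)
  }
  validate_equal_k(configs)
  configs
}

read_landmarks_nts <- function(path, bone_id) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*\"", lines)]       # comment lines
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_mh("NTS parse error: no data in ", path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(header) < 4L)
    stop_mh("NTS parse error at line 1: header needs at least 4 fields")
  n_field <- header[2]
  labeled <- grepl("L$", n_field, ignore.case = TRUE)
  n <- as.integer(sub("L$", "", n_field, ignore.case = TRUE))
  p <- as.integer(header[3])
  dim_m <- regmatches(header, regexec("^dim=([0-9]+)$", header,
                                      ignore.case = TRUE))
  dims <- 3L
  for (d in dim_m) if (length(d)) dims <- as.integer(d[2])
  if (dims != 3L) stop_mh("NTS parse error: only dim=3 data supported")
  if (is.na(n) || is.na(p) || p %% dims != 0L)
    stop_mh("NTS parse error: inconsistent header counts")
  k <- p %/% dims
  body <- lines[-1]
  labels <- sprintf("specimen_%03d", seq_len(n))
  if (labeled) {
    lab_tokens <- strsplit(trimws(paste(body, collapse = " ")), "[ \t]+")[[1]]
    labels <- lab_tokens[seq_len(n)]
    values <- suppressWarnings(as.numeric(lab_tokens[-seq_len(n)]))
  } else {
    values <- suppressWarnings(
      as.numeric(strsplit(trimws(paste(body, collapse = " ")), "[ \t]+")[[1]]))
  }
  if (any(is.na(values)) || length(values) != n * p)
    stop_mh("NTS parse error: expected ", n * p,
            " numeric values, found ", sum(!is.na(values)))
  lapply(seq_len(n), function(i) {
    row <- values[((i - 1L) * p + 1L):(i * p)]
    landmark_config(labels[i], bone_id, unflatten_config(row, k))
  })
}

read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "bone_id", "landmark_id", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_mh("CSV parse error: missing columns ", paste(missing, collapse = ", "))
  for (col in c("x", "y", "z")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_mh("CSV parse error: non-numeric value in column '", col,
              "' at data row ", bad)
    }
  }
  split_keys <- interaction(df$specimen_id, df$bone_id, drop = TRUE, sep = "\r")
  configs <- lapply(split(df, split_keys), function(block) {
    landmark_config(block$specimen_id[1], block$bone_id[1],
                    cbind(block$x, block$y, block$z),
                    landmark_ids = as.character(block$landmark_id))
  })
  names(configs) <- NULL
  validate_equal_k(configs)
  configs
}

validate_equal_k <- function(configs) {
  by_bone <- split(configs, vapply(configs, `[[`, "", "bone_id"))
  for (bone in names(by_bone)) {
    ks <- vapply(by_bone[[bone]], function(cf) nrow(cf$coords), 0L)
    if (length(unique(ks)) > 1L)
      stop_mh("ragged landmark counts within bone '", bone, "': ",
              paste(sort(unique(ks)), collapse = ", "))
  }
  invisible(configs)
}

#' Write landmark configurations to file
#'
#' Inverse of [read_landmarks()]; round-trips coordinates losslessly (full
#' double precision is written).
#'
#' @param configs List of [landmark_config] objects.
#' @param path Output file path.
#' @param format One of `"tps"`, `"nts"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(configs, path, format = c("tps", "nts", "csv")) {
  format <- match.arg(format)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (format == "tps") {
    out <- unlist(lapply(configs, function(cf) {
      c(sprintf("LM3=%d", nrow(cf$coords)),
        apply(cf$coords, 1, function(r) paste(fmt(r), collapse = " ")),
        sprintf("ID=%s", cf$specimen_id))
    }))
    writeLines(out, path)
  } else if (format == "nts") {
    validate_equal_k(configs)
    k <- nrow(configs[[1]]$coords)
    out <- c(sprintf("1 %dL %d 0 dim=3", length(configs), 3L * k),
             vapply(configs, `[[`, "", "specimen_id"),
             vapply(configs, function(cf)
               paste(fmt(flatten_config(cf$coords)), collapse = " "), ""))
    writeLines(out, path)
  } else {
    rows <- do.call(rbind, lapply(configs, function(cf) {
      data.frame(specimen_id = cf$specimen_id, bone_id = cf$bone_id,
                 landmark_id = rownames(cf$coords),
                 x = cf$coords[, 1], y = cf$coords[, 2], z = cf$coords[, 3],
                 stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Assemble a study dataset
#'
#' Bundles specimen metadata with per-bone landmark configurations. Within
#' each bone all configurations must share the same ordered landmark set;
#' coordinates are stored as a k x 3 x n array per bone.
#'
#' @param specimens Data frame with columns `specimen_id`, `group`
#'   (donkey/horse/hybrid or any labels), and optionally `hybrid_class`
#'   (mule/hinny, only for hybrids), `sex` (female/male/gelding), `breed`.
#' @param configurations List of [landmark_config] objects.
#' @param exclusions Named list mapping bone_id to landmark_ids to drop before
#'   analysis (applied by [apply_exclusions()], not here).
#' @return An object of class `study_dataset` with elements `specimens`,
#'   `bones` (named list of k x 3 x n arrays) and `exclusions`.
#' @export
study_dataset <- function(specimens, configurations, exclusions = list()) {
  specimens <- as.data.frame(specimens, stringsAsFactors = FALSE)
  if (!all(c("specimen_id", "group") %in% names(specimens)))
    stop_mh("specimens needs columns 'specimen_id' and 'group'")
  if (anyDuplicated(specimens$specimen_id))
    stop_mh("duplicated specimen_id in specimens table")
  if (any(is.na(specimens$group)))
    stop_mh("group must be determined for every specimen")
  if ("hybrid_class" %in% names(specimens)) {
    bad <- !is.na(specimens$hybrid_class) & specimens$group != "hybrid"
    if (any(bad))
      stop_mh("hybrid_class present for non-hybrid specimen(s): ",
              paste(specimens$specimen_id[bad], collapse = ", "))
  }
  validate_equal_k(configurations)
  spec_ids <- vapply(configurations, `[[`, "", "specimen_id")
  unknown <- setdiff(spec_ids, specimens$specimen_id)
  if (length(unknown))
    stop_mh("configurations reference unknown specimens: ",
            paste(unique(unknown), collapse = ", "))
  by_bone <- split(configurations, vapply(configurations, `[[`, "", "bone_id"))
  bones <- lapply(by_bone, function(cfs) {
    lm_ids <- rownames(cfs[[1]]$coords)
    for (cf in cfs)
      if (!identical(rownames(cf$coords), lm_ids))
        stop_mh("landmark order differs across configurations of bone '",
                cf$bone_id, "'")
    arr <- array(NA_real_, dim = c(nrow(cfs[[1]]$coords), 3L, length(cfs)),
                 dimnames = list(lm_ids, c("x", "y", "z"),
                                 vapply(cfs, `[[`, "", "specimen_id")))
    for (i in seq_along(cfs)) arr[, , i] <- cfs[[i]]$coords
    arr
  })
  structure(list(specimens = specimens, bones = bones,
                 exclusions = exclusions),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Study dataset:", nrow(x$specimens), "specimens,",
      length(x$bones), "bones\n")
  tab <- table(x$specimens$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  for (b in names(x$bones))
    cat(sprintf("  %-18s k=%d n=%d\n", b, dim(x$bones[[b]])[1],
                dim(x$bones[[b]])[3]))
  invisible(x)
}

#' Remove excluded landmarks from a study dataset
#'
#' Drops, per bone, the landmarks named in the exclusion lists (e.g. landmarks
#' unavailable on fragmentary material) so that all retained configurations of
#' a bone share an identical landmark set. Idempotent.
#'
#' @param dataset A [study_dataset].
#' @param exclusions Named list `bone_id -> landmark_ids`; defaults to the
#'   dataset's own exclusion lists.
#' @return The reduced [study_dataset] (with empty exclusion lists).
#' @export
apply_exclusions <- function(dataset, exclusions = dataset$exclusions) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (length(exclusions) == 0L) return(dataset)
  for (bone in names(exclusions)) {
    drop_ids <- exclusions[[bone]]
    if (length(drop_ids) == 0L) next
    if (!bone %in% names(dataset$bones))
      stop_mh("exclusion list names unknown bone '", bone, "'")
    arr <- dataset$bones[[bone]]
    unknown <- setdiff(drop_ids, dimnames(arr)[[1]])
    if (length(unknown))
      stop_mh("unknown landmark id(s) for bone '", bone, "': ",
              paste(unknown, collapse = ", "))
    keep <- setdiff(dimnames(arr)[[1]], drop_ids)
    if (length(keep) < 4L)
      stop_mh("exclusions leave fewer than 4 landmarks for bone '", bone, "'")
    dataset$bones[[bone]] <- arr[keep, , , drop = FALSE]
  }
  dataset$exclusions <- list()
  dataset
}

#' Pool mules and hinnies into a single hybrid group
#'
#' With small hybrid samples the two reciprocal crosses are analyzed as one
#' group; `hybrid_class` is retained for reporting.
#'
#' @param dataset A [study_dataset].
#' @param pool If `TRUE` (default) the analysis label of mules and hinnies is
#'   set to `"hybrid"`; if `FALSE`, `group` is set to the hybrid class so the
#'   two strata are analyzed separately.
#' @return The relabelled [study_dataset].
#' @export
pool_hybrids <- function(dataset, pool = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  sp <- dataset$specimens
  if (!"hybrid_class" %in% names(sp)) return(dataset)
  is_hy <- !is.na(sp$hybrid_class)
  if (pool) {
    sp$group[is_hy] <- "hybrid"
  } else {
    sp$group[is_hy] <- sp$hybrid_class[is_hy]
  }
  dataset$specimens <- sp
  dataset
}

#' Extract one bone's coordinate array and matching metadata
#'
#' @param dataset A [study_dataset].
#' @param bone_id Bone to extract.
#' @return List with `coords` (k x 3 x n array) and `specimens` (metadata rows
#'   in the same specimen order).
#' @export
bone_sample <- function(dataset, bone_id) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!bone_id %in% names(dataset$bones))
    stop_mh("bone '", bone_id, "' not present in dataset")
  arr <- dataset$bones[[bone_id]]
  ids <- dimnames(arr)[[3]]
  meta <- dataset$specimens[match(ids, dataset$specimens$specimen_id), ,
                            drop = FALSE]
  rownames(meta) <- NULL
  list(coords = arr, specimens = meta)
}

#' Mirror configurations for antimere comparability
#'
#' Reflects the first coordinate axis of the flagged configurations so that
#' left- and right-side bones can enter a common, proper-rotation-only
#' superimposition.
#'
#' @param coords k x 3 x n coordinate array.
#' @param reflect Logical vector of length n flagging configurations to mirror.
#' @return The (partially) mirrored array.
#' @export
reflect_configurations <- function(coords, reflect) {
  stopifnot(length(reflect) == dim(coords)[3])
  for (i in which(reflect)) coords[, 1, i] <- -coords[, 1, i]
  coords
}
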