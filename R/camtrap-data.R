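#' Development-gradient classification from housing density
#'
#' Classifies housing density (houses/km^2) into the five development
#' levels of the urban-wild gradient. The published bins do not tile the
#' real line (e.g. nothing between 0.5 and 0.51), so the package adopts a
#' half-open convention that contains every published bin:
#' wild \[0, 0.5), rural \[0.5, 12.64), exurban \[12.64, 147.048),
#' suburban \[147.048, 1000\], urban (1000, Inf).
#'
#' @param housing_density numeric vector, houses per km^2, non-negative.
#' @return factor with levels `urban, suburban, exurban, rural, wild`
#'   (ordered most to least developed).
#' @export
#' @examples
#' classify_development(c(0.4, 5, 100, 500, 1500))
classify_development <- function(housing_density) {
  if (any(is.na(housing_density)) || any(housing_density < 0))
    stop("housing_density must be non-negative and non-missing")
  lev <- ifelse(housing_density < 0.5, "wild",
         ifelse(housing_density < 12.64, "rural",
         ifelse(housing_density < 147.048, "exurban",
         ifelse(housing_density <= 1000, "suburban", "urban"))))
  factor(lev, levels = development_levels())
}

#' Gradient and plot-type level sets
#'
#' Canonical ordered level sets used throughout the package: development
#' levels run from most to least developed (urban -> wild).
#' @return character vector of level names.
#' @export
development_levels <- function() c("urban", "suburban", "exurban", "rural", "wild")

#' @rdname development_levels
#' @export
plot_types <- function() c("large_forest", "small_forest", "open", "yard")

parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out  # NA where no format matched; callers warn and drop
}

#' Collapse photo records into independent detection sequences
#'
#' Consecutive photos of the same species at the same camera site are
#' merged into one sequence (one independent detection) whenever the gap
#' to the previous photo is strictly less than `gap_seconds`. A gap of
#' exactly `gap_seconds` starts a new sequence. The sequence timestamp is
#' the first photo's; the sequence `animal_count` is the maximum
#' simultaneous count seen in any photo of the sequence (animals in the
#' sequence, not photos). The operation is idempotent.
#'
#' @param records data.frame with columns `site_id`, `timestamp`
#'   (POSIXct or ISO-8601 text), `species`, and optionally `animal_count`
#'   (defaults to 1). Records with unparseable timestamps are dropped
#'   with a warning.
#' @param gap_seconds independence gap in seconds (default 60).
#' @return data.frame of sequences: `site_id`, `species`, `timestamp`
#'   (first photo), `animal_count` (max simultaneous), `n_photos`.
#' @export
collapse_sequences <- function(records, gap_seconds = 60) {
  stopifnot(is.data.frame(records), gap_seconds > 0)
  need <- c("site_id", "timestamp", "species")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (is.null(records$animal_count)) records$animal_count <- 1L
  if (any(records$animal_count < 1)) stop("animal_count must be >= 1")

  ts <- suppressWarnings(parse_timestamps(records$timestamp))
  bad <- is.na(ts)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable timestamps dropped")
    records <- records[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  if (nrow(records) == 0L)
    return(data.frame(site_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      animal_count = integer(), n_photos = integer()))
  ord <- order(records$site_id, records$species, ts)
  records <- records[ord, , drop = FALSE]
  ts <- ts[ord]

  grp <- paste(records$site_id, records$species, sep = "\r")
  gap <- c(Inf, diff(as.numeric(ts)))
  gap[c(TRUE, grp[-1L] != grp[-length(grp)])] <- Inf
  if (any(gap < 0))
    stop("timestamps out of order (clock disorder) at site ",
         records$site_id[which(gap < 0)[1L]])
  seq_id <- cumsum(gap >= gap_seconds)

  first <- !duplicated(seq_id)
  fseq <- factor(seq_id, levels = unique(seq_id))  # keep occurrence order
  out <- data.frame(
    site_id = records$site_id[first],
    species = records$species[first],
    timestamp = ts[first],
    animal_count = as.integer(tapply(records$animal_count, fseq, max)),
    n_photos = as.integer(tabulate(fseq)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

site_nights <- function(sites) {
  start <- as.Date(sites$deploy_start)
  end <- as.Date(sites$deploy_end)
  if (any(end < start)) stop("deploy_end before deploy_start at site ",
                             sites$site_id[which(end < start)[1L]])
  as.integer(end - start) + 1L  # partial first/last days count as full nights
}

#' Build daily detection histories from independent sequences
#'
#' Collapses independent detection sequences into a species x site x day
#' binary array. Day 1 is each site's deployment start date; days are cut
#' at local midnight. The effort mask marks the days each camera was
#' deployed; cells outside a site's deployment are 0 with effort 0.
#' Records dated outside their site's deployment window are dropped with
#' a warning.
#'
#' @param records data.frame of independent sequences (from
#'   [collapse_sequences()]), columns `site_id`, `timestamp`, `species`.
#' @param sites site table with `site_id`, `deploy_start`, `deploy_end`.
#' @param species optional character vector fixing the species axis
#'   (defaults to species present in `records`, sorted).
#' @return an object of class `detection_history`: list with `Y`
#'   (S x I x D binary array), `effort` (I x D binary matrix), `species`,
#'   `site_id`, `nights` (per-site camera-nights).
#' @export
build_detection_history <- function(records, sites, species = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(sites))
  if (anyDuplicated(sites$site_id)) stop("duplicated site_id in sites")
  species <- species %||% sort(unique(as.character(records$species)))
  nights <- site_nights(sites)
  I <- nrow(sites); D <- max(nights, 1L); S <- length(species)

  effort <- matrix(0L, I, D)
  for (i in seq_len(I)) effort[i, seq_len(nights[i])] <- 1L

  Y <- array(0L, dim = c(S, I, D),
             dimnames = list(species = species, site = sites$site_id, day = NULL))
  if (nrow(records)) {
    ts <- parse_timestamps(records$timestamp)
    isite <- match(records$site_id, sites$site_id)
    if (any(is.na(isite))) stop("record at unknown site ",
                                records$site_id[which(is.na(isite))[1L]])
    day <- as.integer(as.Date(ts) - as.Date(sites$deploy_start)[isite]) + 1L
    ispec <- match(as.character(records$species), species)
    keep <- !is.na(ispec) & day >= 1L & day <= nights[isite]
    if (any(!is.na(ispec) & !keep))
      warning(sum(!is.na(ispec) & !keep),
              " record(s) outside deployment windows dropped")
    Y[cbind(ispec[keep], isite[keep], day[keep])] <- 1L
  }
  structure(list(Y = Y, effort = effort, species = species,
                 site_id = sites$site_id, nights = nights),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat("Detection history:", length(x$species), "species x",
      length(x$site_id), "sites x", ncol(x$effort), "days;",
      sum(x$nights), "camera-nights,", sum(x$Y), "detection-days\n")
  invisible(x)
}

#' Naive occupancy per species
#'
#' Fraction of sites with at least one detection of each species,
#' uncorrected for imperfect detection, plus the community mean, min and
#' max across species.
#'
#' @param history a [build_detection_history()] object.
#' @return list with `per_species` (named vector), `mean`, `min`, `max`.
#' @export
naive_occupancy <- function(history) {
  stopifnot(inherits(history, "detection_history"))
  if (length(history$site_id) == 0L) stop("empty detection history")
  per <- apply(history$Y, 1L, function(m) mean(rowSums(m) > 0))
  names(per) <- history$species
  list(per_species = per, mean = mean(per), min = min(per), max = max(per))
}

#' Detection rates per species and site
#'
#' Independent detections divided by camera-nights, the relative
#' abundance index. Every (species, site) pair in scope is reported,
#' including zeros.
#'
#' @param records independent sequences (from [collapse_sequences()]).
#' @param sites site table with deployment dates.
#' @param species species subset, or `"all"` to pool all species into a
#'   single total-mammal rate; default all species present, unpooled.
#' @param per_animal if `TRUE`, count total animals (sum of sequence
#'   `animal_count`) instead of sequences.
#' @return data.frame: `species`, `site_id`, `detections`,
#'   `camera_nights`, `rate`.
#' @export
detection_rates <- function(records, sites, species = NULL, per_animal = FALSE) {
  nights <- site_nights(sites)
  if (any(nights <= 0)) stop("zero camera-nights at site ",
                             sites$site_id[which(nights <= 0)[1L]])
  pooled <- identical(species, "all")
  recs <- records
  if (!pooled && !is.null(species))
    recs <- recs[recs$species %in% species, , drop = FALSE]
  sp <- if (pooled) "all" else species %||% sort(unique(as.character(records$species)))
  w <- if (per_animal && nrow(recs)) recs$animal_count else rep(1L, nrow(recs))

  grid <- expand.grid(species = sp, site_id = sites$site_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- if (pooled) recs$site_id else paste(recs$species, recs$site_id, sep = "\r")
  gkey <- if (pooled) grid$site_id else paste(grid$species, grid$site_id, sep = "\r")
  det <- as.numeric(rowsum(as.numeric(w), key)[match(gkey, sort(unique(key))), 1L])
  det[is.na(det)] <- 0
  grid$detections <- det
  grid$camera_nights <- nights[match(grid$site_id, sites$site_id)]
  grid$rate <- grid$detections / grid$camera_nights
  grid
}

#' Effort-corrected detection profile across the gradient
#'
#' For each species, the within-level detection rate
#' (detections / camera-nights pooled over the level's sites) is
#' normalized across sampled development levels to percentages summing to
#' 100, so that unequal effort between levels does not distort where a
#' species is detected.
#'
#' @param records independent sequences.
#' @param sites site table with `development_level` and deployment dates.
#' @param species optional species subset.
#' @return data.frame `species`, `development_level`, `rate`, `percent`.
#'   Species never detected get `NA` percentages and are listed in the
#'   `"flagged"` attribute.
#' @export
effort_weighted_detection_profile <- function(records, sites, species = NULL) {
  lev <- factor(sites$development_level, levels = development_levels())
  nights <- site_nights(sites)
  nights_lev <- tapply(nights, lev, sum)
  sampled <- names(nights_lev)[!is.na(nights_lev) & nights_lev > 0]
  if (length(sampled) == 0L) stop("no development level with nonzero effort")
  sp <- species %||% sort(unique(as.character(records$species)))

  out <- expand.grid(species = sp, development_level = sampled,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec_lev <- as.character(lev)[match(records$site_id, sites$site_id)]
  key <- paste(records$species, rec_lev, sep = "\r")
  okey <- paste(out$species, out$development_level, sep = "\r")
  cnt <- table(key)
  out$detections <- as.numeric(cnt[okey]); out$detections[is.na(out$detections)] <- 0
  out$rate <- out$detections / as.numeric(nights_lev[out$development_level])
  tot <- tapply(out$rate, out$species, sum)[out$species]
  out$percent <- ifelse(tot > 0, 100 * out$rate / tot, NA_real_)
  flagged <- unique(out$species[is.na(out$percent)])
  out$development_level <- factor(out$development_level, levels = development_levels())
  out <- out[order(out$species, out$development_level), ]
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

#' Read and validate a detections CSV
#'
#' Schema: `site_id`, `timestamp` (ISO-8601), `species`, `count`.
#' @param path file path.
#' @return data.frame with `animal_count` standardized.
#' @export
read_detections <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "timestamp", "species")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("detections file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(x$count) && is.null(x$animal_count)) x$animal_count <- x$count
  x$animal_count <- x$animal_count %||% 1L
  x
}

#' Read and validate a sites CSV
#'
#' Required: `site_id`, `housing_density`, `deploy_start`, `deploy_end`;
#' `development_level` is derived from density when absent.
#' @param path file path.
#' @return site table data.frame.
#' @export
read_sites <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "housing_density", "deploy_start", "deploy_end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sites file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$site_id)) stop("duplicated site_id in sites file")
  x$deploy_start <- as.Date(x$deploy_start)
  x$deploy_end <- as.Date(x$deploy_end)
  if (is.null(x$development_level))
    x$development_level <- classify_development(x$housing_density)
  x
}
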