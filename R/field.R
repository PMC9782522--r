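#' Specify one broadcast-seeded test row
#'
#' A row is a `length` x `width` rectangle of ground with weeds and crop
#' plants scattered uniformly at the given densities. The field trials this
#' emulates used three adjacent 0.5 m x 10 m rows at roughly 6.6, 17.8 and
#' 11.8 weeds/m2; the crop (soybean) density follows the seeding rate of
#' 395,000 seeds/ha, i.e. 39.5 plants/m2 at full emergence.
#'
#' @param length row length along the travel direction, metres.
#' @param width row width across the travel direction, metres.
#' @param weed_density weeds per square metre.
#' @param soy_density crop plants per square metre.
#' @param emergence fraction of sown crop seeds that emerge, in `[0, 1]`.
#' @return A `row_spec` object.
#' @export
row_spec <- function(length = 10, width = 0.5, weed_density = 11.8,
                     soy_density = 39.5, emergence = 1) {
  if (length <= 0 || width <= 0) stop_param("row length and width must be > 0")
  if (weed_density < 0 || soy_density < 0) stop_param("densities must be >= 0")
  if (emergence < 0 || emergence > 1) stop_param("emergence must be in [0, 1]")
  structure(
    list(length = length, width = width, weed_density = weed_density,
         soy_density = soy_density * emergence),
    class = "row_spec")
}

#' Generate a synthetic field plot with ground-truth plant positions
#'
#' Plants are placed by a homogeneous Poisson process: the count per species
#' is Poisson(density x area) (or the rounded expectation when
#' `exact_counts = TRUE`, which reproduces fixed trial populations such as
#' 33/89/59 weeds on 6.6/17.8/11.8 weeds/m2 rows of 5 m2), and positions are
#' uniform over the row rectangle. Canopy radii are lognormal; they only
#' matter for bounding-box size and footprint hit tests and are synthetic.
#'
#' @param specs a `row_spec` or list of them (one per adjacent row).
#' @param seed integer; fixes all randomness.
#' @param exact_counts logical; use `round(density * area)` plants instead of
#'   a Poisson draw.
#' @param radius_meanlog,radius_sdlog lognormal parameters of plant canopy
#'   radius in metres (default median 0.04 m).
#' @return A `field_plot`: list with `rows` (data.frame of row geometry) and
#'   `plants` (data.frame with columns `id`, `row`, `species`, `x`, `y`,
#'   `radius`, `is_sample`, `is_without_weed`). `x` is metres along travel in
#'   `[0, length)`, `y` metres across the row centred on 0.
#' @export
generate_field <- function(specs, seed, exact_counts = FALSE,
                           radius_meanlog = log(0.04), radius_sdlog = 0.25) {
  if (inherits(specs, "row_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "row_spec")))
  rows <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(row = i, length = s$length, width = s$width,
               weed_density = s$weed_density, soy_density = s$soy_density)
  }))
  plants <- with_seed(derive_seed(seed, "field"), {
    out <- list()
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      area <- s$length * s$width
      for (sp in c("weed", "soybean")) {
        dens <- if (sp == "weed") s$weed_density else s$soy_density
        n <- if (exact_counts) as.integer(round(dens * area)) else
          stats::rpois(1L, dens * area)
        if (n == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          row = i, species = sp,
          x = stats::runif(n, 0, s$length),
          y = stats::runif(n, -s$width / 2, s$width / 2),
          radius = stats::rlnorm(n, radius_meanlog, radius_sdlog))
      }
    }
    if (length(out) == 0L) {
      data.frame(row = integer(), species = character(), x = numeric(),
                 y = numeric(), radius = numeric())
    } else do.call(rbind, out)
  })
  plants <- plants[order(plants$row, plants$x), , drop = FALSE]
  plants <- cbind(id = seq_len(nrow(plants)), plants)
  plants$is_sample <- logical(nrow(plants))
  plants$is_without_weed <- logical(nrow(plants))
  rownames(plants) <- NULL
  structure(list(rows = rows, plants = plants), class = "field_plot")
}

#' Across-row global y coordinate of each plant
#'
#' Adjacent rows are laid side by side; row `i`'s centreline sits at the
#' cumulative width offset. Used for adjacency tests and footprint spill
#' across row boundaries (the nozzle pattern is wider than one row).
#'
#' @param plot a `field_plot`.
#' @return Numeric vector, one value per plant, metres.
#' @export
global_y <- function(plot) {
  w <- plot$rows$width
  offset <- c(0, cumsum(w))[plot$plants$row] + w[plot$plants$row] / 2
  offset + plot$plants$y
}

#' Mark random weed and crop samples and label crops without adjacent weeds
#'
#' Reproduces the field-trial protocol: a fixed number of target weeds and
#' non-target crop plants are drawn at random across all rows, and a sampled
#' crop plant is labelled "without weeds" iff no weed (sampled or not) lies
#' within `adjacency_radius` of it in the across-row plane.
#'
#' @param plot a `field_plot`.
#' @param n_weed,n_soy number of samples per species (trial protocol: 30/30).
#' @param adjacency_radius metres; a crop plant has an "adjacent weed" iff
#'   some weed is within this distance. The trials never quantified
#'   adjacency; the default 0.15 m is on the scale of the spray footprint
#'   half-width per row.
#' @param seed integer; fixes the sample draw.
#' @return The `field_plot` with `is_sample` / `is_without_weed` set.
#' @export
mark_samples <- function(plot, n_weed = 30, n_soy = 30,
                         adjacency_radius = 0.15, seed = 1L) {
  p <- plot$plants
  widx <- which(p$species == "weed")
  sidx <- which(p$species == "soybean")
  if (length(widx) < n_weed || length(sidx) < n_soy) {
    stop_param("not enough plants to sample: have ", length(widx), " weeds / ",
               length(sidx), " soybeans, need ", n_weed, " / ", n_soy)
  }
  sel <- with_seed(derive_seed(seed, "samples"), {
    list(w = sample(widx, n_weed), s = sample(sidx, n_soy))
  })
  p$is_sample <- FALSE
  p$is_sample[c(sel$w, sel$s)] <- TRUE
  gy <- global_y(plot)
  p$is_without_weed <- FALSE
  if (length(widx) == 0L) {
    p$is_without_weed[sel$s] <- TRUE
  } else {
    for (i in sel$s) {
      d2 <- (p$x[widx] - p$x[i])^2 + (gy[widx] - gy[i])^2
      p$is_without_weed[i] <- !any(d2 <= adjacency_radius^2)
    }
  }
  plot$plants <- p
  plot
}

#' Sample id sets of a marked plot
#'
#' @param plot a `field_plot` after [mark_samples()].
#' @return List with integer vectors `weed`, `soy`, `soy_without_weed`.
#' @export
sample_ids <- function(plot) {
  p <- plot$plants
  list(weed = p$id[p$is_sample & p$species == "weed"],
       soy = p$id[p$is_sample & p$species == "soybean"],
       soy_without_weed = p$id[p$is_without_weed])
}

#' @export
print.field_plot <- function(x, ...) {
  p <- x$plants
  cat("<field_plot> ", nrow(x$rows), " row(s), ",
      sum(p$species == "weed"), " weeds, ",
      sum(p$species == "soybean"), " soybeans",
      if (any(p$is_sample)) paste0(" (", sum(p$is_sample & p$species == "weed"),
                                   "+", sum(p$is_sample & p$species == "soybean"),
                                   " sampled)"), "\n", sep = "")
  invisible(x)
}

#' Write / read a field plot as flat CSV
#'
#' Columns: id, row, species, x, y, radius, is_sample, is_without_weed.
#' Coordinates in metres, x half-open in `[0, length)`.
#'
#' @param plot a `field_plot`.
#' @param path file path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   needs the original `rows` geometry, supplied as `rows`.
#' @param rows data.frame of row geometry as in `plot$rows`.
#' @export
write_field_csv <- function(plot, path) {
  utils::write.csv(plot$plants, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, rows) {
  plants <- utils::read.csv(path, stringsAsFactors = FALSE)
  plants$is_sample <- as.logical(plants$is_sample)
  plants$is_without_weed <- as.logical(plants$is_without_weed)
  structure(list(rows = rows, plants = plants), class = "field_plot")
}

#' Serialize a field plot to / from JSON
#'
#' @param plot a `field_plot`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
field_to_json <- function(plot, path = NULL) {
  x <- list(rows = plot$rows, plants = plot$plants)
  if (is.null(path)) {
    jsonlite::toJSON(x, dataframe = "columns", digits = NA)
  } else {
    jsonlite::write_json(x, path, dataframe = "columns", digits = NA)
    invisible(path)
  }
}

#' @rdname field_to_json
#' @param json JSON string or file path produced by [field_to_json()].
#' @export
field_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(rows = as.data.frame(x$rows),
                 plants = as.data.frame(x$plants)),
            class = "field_plot")
}
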