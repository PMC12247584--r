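#' Default 17-network cortical layout
#'
#' Parcel counts per network for the default atlas preset: 400 cortical
#' parcels across the 17 canonical networks of the Schaefer/Yeo taxonomy.
#' DefaultC (the memory-linked DMN-C subnetwork) has 13 parcels and DefaultA
#' (DMN-A) has 34; the remaining 353 parcels are distributed over the other
#' 15 networks with plausible sizes.
#'
#' @return named integer vector of parcel counts summing to 400.
#' @export
schaefer17_sizes <- function() {
  c(VisCent = 24L, VisPeri = 22L, SomMotA = 38L, SomMotB = 28L,
    DorsAttnA = 22L, DorsAttnB = 22L, SalVentAttnA = 25L, SalVentAttnB = 21L,
    LimbicA = 12L, LimbicB = 12L, ContA = 25L, ContB = 25L, ContC = 12L,
    DefaultA = 34L, DefaultB = 36L, DefaultC = 13L, TempPar = 29L)
}

#' Build an atlas label table
#'
#' Constructs the ROI bookkeeping table used throughout the pipeline: one row
#' per ROI with its name, hemisphere, network label, and derived analysis role
#' (`DMN-C`, `DMN-A`, `Hipp`, or `other`). The default arguments reproduce the
#' study layout: 400 cortical parcels in 17 networks plus 6 hippocampal ROIs
#' (head/body/tail in each hemisphere), a 406-ROI connectome.
#'
#' Hemisphere splits follow the published network memberships where stated
#' (DMN-C 7 left / 6 right, DMN-A 18 left / 16 right); other networks are
#' split as evenly as possible with the extra parcel on the left.
#'
#' @param network_sizes named vector of parcel counts per cortical network
#'   (at least two networks, all positive).
#' @param hippocampus_size number of hippocampal ROIs (0 to skip; the default
#'   6 gives head/body/tail x hemisphere).
#' @param role_map list naming which network labels play the `dmn_c`,
#'   `dmn_a` and `hipp` roles.
#' @return a `data.frame` with columns `roi_id`, `roi_name`, `hemisphere`
#'   (`"L"`, `"R"` or `NA`), `network`, `role`; class `atlas_labels`.
#' @export
make_atlas <- function(network_sizes = schaefer17_sizes(),
                       hippocampus_size = 6,
                       role_map = list(dmn_c = "DefaultC", dmn_a = "DefaultA",
                                       hipp = "Hipp")) {
  if (any(network_sizes <= 0) || hippocampus_size < 0) {
    stop("invalid atlas config: network sizes must be positive and hippocampus size non-negative",
         call. = FALSE)
  }
  if (length(network_sizes) < 2) {
    stop("invalid atlas config: at least two cortical networks are required", call. = FALSE)
  }
  if (is.null(names(network_sizes))) {
    names(network_sizes) <- paste0("Net", seq_along(network_sizes))
  }

  # hemisphere counts: published splits for the two DMN subnetworks, even
  # split (left gets the remainder) elsewhere
  left_counts <- ceiling(network_sizes / 2)
  if (role_map$dmn_c %in% names(network_sizes) &&
      network_sizes[[role_map$dmn_c]] == 13L) {
    left_counts[[role_map$dmn_c]] <- 7L
  }
  if (role_map$dmn_a %in% names(network_sizes) &&
      network_sizes[[role_map$dmn_a]] == 34L) {
    left_counts[[role_map$dmn_a]] <- 18L
  }

  rows <- lapply(names(network_sizes), function(net) {
    n <- network_sizes[[net]]
    nl <- left_counts[[net]]
    hemi <- c(rep("L", nl), rep("R", n - nl))
    idx <- c(seq_len(nl), seq_len(n - nl))
    data.frame(
      roi_name = paste0(net, "_", hemi, "_", idx),
      hemisphere = hemi,
      network = net,
      stringsAsFactors = FALSE
    )
  })
  atlas <- do.call(rbind, rows)

  if (hippocampus_size > 0) {
    parts <- c("head", "body", "tail")
    hemi <- rep(c("L", "R"), length.out = hippocampus_size)
    part <- parts[((seq_len(hippocampus_size) - 1) %/% 2) %% 3 + 1]
    hip <- data.frame(
      roi_name = paste0("Hipp_", part, "_", hemi),
      hemisphere = hemi,
      network = role_map$hipp,
      stringsAsFactors = FALSE
    )
    atlas <- rbind(atlas, hip)
  }

  atlas$roi_id <- seq_len(nrow(atlas))
  atlas$role <- "other"
  atlas$role[atlas$network == role_map$dmn_c] <- "DMN-C"
  atlas$role[atlas$network == role_map$dmn_a] <- "DMN-A"
  atlas$role[atlas$network == role_map$hipp] <- "Hipp"
  atlas <- atlas[, c("roi_id", "roi_name", "hemisphere", "network", "role")]
  class(atlas) <- c("atlas_labels", "data.frame")
  atlas
}

#' Write / read an atlas label table
#'
#' Plain TSV dialect: columns `roi_id`, `roi_name`, `hemisphere`, `network`
#' (role is re-derived on read so user-supplied tables need not carry it).
#'
#' @param atlas an `atlas_labels` table.
#' @param path file path.
#' @param role_map see [make_atlas()].
#' @return `read_atlas` returns an `atlas_labels` table.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas[, c("roi_id", "roi_name", "hemisphere", "network")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path, role_map = list(dmn_c = "DefaultC", dmn_a = "DefaultA",
                                             hipp = "Hipp")) {
  atlas <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("roi_id", "roi_name", "hemisphere", "network")
  if (!all(need %in% names(atlas))) {
    stop("atlas file missing columns: ", paste(setdiff(need, names(atlas)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(atlas$roi_id)) stop("duplicate roi_id in atlas", call. = FALSE)
  atlas$role <- "other"
  atlas$role[atlas$network == role_map$dmn_c] <- "DMN-C"
  atlas$role[atlas$network == role_map$dmn_a] <- "DMN-A"
  atlas$role[atlas$network == role_map$hipp] <- "Hipp"
  class(atlas) <- c("atlas_labels", "data.frame")
  atlas
}
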