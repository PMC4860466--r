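#' Save and restore a fitted model
#'
#' `write_bilexnet()` serialises the full model state (map weights,
#' associative and lateral matrices, registries, logs and configuration)
#' into a single compressed archive together with a version header and an
#' MD5 checksum of the payload; `read_bilexnet()` verifies the checksum and
#' restores a bit-identical model, so naming outputs before saving equal
#' naming outputs after loading.
#'
#' @param model A fitted [bilexnet()] model.
#' @param path File path of the archive.
#' @return `write_bilexnet()` returns `path` invisibly; `read_bilexnet()`
#'   returns the restored `bilexnet` object.
#' @export
write_bilexnet <- function(model, path) {
  stopifnot(inherits(model, "bilexnet"))
  payload <- serialize(model, NULL, xdr = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(payload, tmp)
  md5 <- unname(tools::md5sum(tmp))
  archive <- list(format = "bilexnet-state", version = 1L,
                  package_version = as.character(utils::packageVersion("bilexnet")),
                  md5 = md5, payload = payload)
  saveRDS(archive, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_bilexnet
#' @export
read_bilexnet <- function(path) {
  archive <- tryCatch(readRDS(path), error = function(e)
    stop(errorCondition(sprintf("corrupt or unreadable archive: %s", conditionMessage(e)),
                        class = c("bilexnet_corrupt_archive", "bilexnet_error", "error"))))
  if (!is.list(archive) || !identical(archive$format, "bilexnet-state"))
    stop(errorCondition("not a bilexnet state archive",
                        class = c("bilexnet_corrupt_archive", "bilexnet_error", "error")))
  if (!identical(archive$version, 1L))
    stop(errorCondition(sprintf("unsupported archive version %s", archive$version),
                        class = c("bilexnet_version_mismatch", "bilexnet_error", "error")))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(archive$payload, tmp)
  if (!identical(unname(tools::md5sum(tmp)), archive$md5))
    stop(errorCondition("archive checksum mismatch",
                        class = c("bilexnet_corrupt_archive", "bilexnet_error", "error")))
  unserialize(archive$payload)
}
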