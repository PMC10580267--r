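index_fixture <- function(td, use_piscem = FALSE, ref_type = "splici") {
  tg <- gen_toy_genome(seed = 21L, n_genes = 3L, isoforms_per_gene = 2L,
                       out_dir = file.path(td, "inputs"))
  cmd_index(list(out_dir = file.path(td, "idx"), ref_type = ref_type,
                 genome_fasta = tg$files$genome, gtf = tg$files$gtf,
                 rlen = 91L, use_piscem = use_piscem))
}

test_that("index records the backend and persists a readable manifest", {
  td <- withr::local_tempdir()
  res <- index_fixture(td, use_piscem = TRUE)
  expect_identical(res$manifest$backend, "piscem")
  expect_identical(res$plan$stages[[1L]]$argv[[1L]], "piscem")

  m <- read_manifest(file.path(td, "idx"))
  expect_identical(m$backend, "piscem")
  expect_identical(m$ref_type, "splici")
  expect_true(file.exists(m$paths$reference_fasta))
  expect_true(file.exists(m$paths$t2g))
  # ref_type recorded identically in manifest and reference metadata
  meta <- jsonlite::read_json(file.path(td, "idx", "ref",
                                        "ref_metadata.json"))
  expect_identical(meta$ref_type, m$ref_type)

  td2 <- withr::local_tempdir()
  res2 <- index_fixture(td2)
  expect_identical(res2$manifest$backend, "salmon")
  expect_identical(res2$plan$stages[[1L]]$argv[[1L]], "salmon")
})

test_that("conflicting or missing reference inputs are rejected", {
  td <- withr::local_tempdir()
  expect_error(cmd_index(list(out_dir = td, ref_type = "splici",
                              genome_fasta = "g.fa", gtf = "a.gtf",
                              rlen = 91L, ref_seq = "r.fa", t2g = "t.tsv")),
               "conflicting")
  expect_error(cmd_index(list(out_dir = td, ref_type = "direct")), "direct")
  expect_error(cmd_index(list(out_dir = td, ref_type = "splici")),
               "genome")
})

test_that("quant chains the indexed backend without user input", {
  td <- withr::local_tempdir()
  index_fixture(td, use_piscem = TRUE)
  plan <- cmd_quant(list(index_dir = file.path(td, "idx"),
                         geometry = "1{b[16]u[12]x:}2{r:}",
                         reads1 = "a_R1.fq", reads2 = "a_R2.fq",
                         out_dir = file.path(td, "q")))
  stage_names <- vapply(plan$stages, `[[`, character(1), "name")
  expect_identical(stage_names,
                   c("map", "generate-permit-list", "collate", "quant"))
  expect_identical(plan$stages[[1L]]$argv[[1L]], "piscem")
  # t2g injected from the manifest
  quant_argv <- plan$stages[[4L]]$argv
  expect_true(read_manifest(file.path(td, "idx"))$paths$t2g %in% quant_argv)
  # no unresolved placeholders anywhere
  for (s in plan$stages) {
    expect_false(any(grepl("\\{[a-z0-9_]+\\}", s$argv)))
  }
})

test_that("plans are byte-identical across repeated invocations", {
  td <- withr::local_tempdir()
  index_fixture(td)
  cfg <- list(index_dir = file.path(td, "idx"), geometry = SCI_GEOM,
              reads1 = "a_R1.fq", reads2 = "a_R2.fq",
              out_dir = file.path(td, "q"))
  expect_identical(cmd_quant(cfg), cmd_quant(cfg))
})

test_that("complex geometries get an xform stage and a simplified mapper geometry", {
  td <- withr::local_tempdir()
  index_fixture(td)
  plan <- cmd_quant(list(index_dir = file.path(td, "idx"),
                         geometry = SCI_GEOM,
                         reads1 = "a_R1.fq", reads2 = "a_R2.fq",
                         out_dir = file.path(td, "q")))
  stage_names <- vapply(plan$stages, `[[`, character(1), "name")
  expect_identical(stage_names[1:2], c("xform", "map"))
  # the mapper never sees the complex geometry string
  map_argv <- plan$stages[[2L]]$argv
  expect_false(SCI_GEOM %in% map_argv)
  expect_true("1{b[20]u[8]}2{r:}" %in% map_argv)
  # xform output pipes feed the mapper
  expect_true(all(plan$stages[[1L]]$io$outputs %in% map_argv))

  simple <- cmd_quant(list(index_dir = file.path(td, "idx"),
                           geometry = "1{b[16]u[12]x:}2{r:}",
                           reads1 = "a_R1.fq", reads2 = "a_R2.fq",
                           out_dir = file.path(td, "q")))
  expect_false("xform" %in% vapply(simple$stages, `[[`, character(1),
                                   "name"))
})

test_that("an existing mapping directory skips xform and map stages", {
  td <- withr::local_tempdir()
  plan <- cmd_quant(list(map_dir = file.path(td, "map"), t2g = "t2g.tsv",
                         out_dir = file.path(td, "q")))
  expect_identical(vapply(plan$stages, `[[`, character(1), "name"),
                   c("generate-permit-list", "collate", "quant"))
  expect_error(cmd_quant(list(out_dir = td)), "index_dir")
})

test_that("plan execution is ordered, aborts on failure, and logs argv", {
  plan <- structure(list(stages = lapply(1:5, function(i) {
    list(name = paste0("s", i), argv = c("tool", as.character(i)),
         io = list())
  }), provenance = NULL), class = "command_plan")

  ex <- recording_executor()
  log <- execute_plan(plan, ex)
  expect_equal(length(ex$calls()), 5L)
  expect_identical(vapply(ex$calls(), `[[`, character(1), 2L),
                   as.character(1:5))
  expect_identical(log$argv, paste("tool", 1:5))
  expect_true(all(log$status == 0L))

  ex2 <- recording_executor(fail_at = 2L)
  err <- tryCatch(execute_plan(plan, ex2), error = function(e) e)
  expect_s3_class(err, "stage_failure")
  expect_identical(err$stage, "s2")
  expect_equal(length(ex2$calls()), 2L)  # stages 3-5 never invoked
})

test_that("direct references are staged verbatim", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "txome.fa")
  writeLines(c(">tx1", "ACGTACGT"), fa)
  t2g <- file.path(td, "t2g.tsv")
  writeLines("tx1\tg1", t2g)
  res <- cmd_index(list(out_dir = file.path(td, "idx"), ref_type = "direct",
                        ref_seq = fa, t2g = t2g))
  expect_identical(res$manifest$ref_type, "direct")
  staged <- res$manifest$paths$reference_fasta
  expect_identical(readLines(staged), readLines(fa))
  expect_identical(readLines(res$manifest$paths$t2g), readLines(t2g))
})
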