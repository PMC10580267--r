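{
  "salmon": {
    "index": ["salmon", "index", "--threads", "{threads}", "-t", "{ref_fasta}", "-i", "{index_dir}", "-k", "31"],
    "map": ["salmon", "alevin", "-l", "ISR", "-i", "{index_dir}", "-1", "{reads1}", "-2", "{reads2}", "--read-geometry", "{geometry}", "--sketch", "-p", "{threads}", "-o", "{map_dir}"]
  },
  "piscem": {
    "index": ["piscem", "build", "-s", "{ref_fasta}", "-k", "31", "-m", "19", "--threads", "{threads}", "-o", "{index_dir}"],
    "map": ["piscem", "map-sc", "-i", "{index_dir}", "-1", "{reads1}", "-2", "{reads2}", "--geometry", "{geometry}", "--threads", "{threads}", "-o", "{map_dir}"]
  },
  "alevin-fry": {
    "generate-permit-list": ["alevin-fry", "generate-permit-list", "-i", "{map_dir}", "-d", "fw", "--unfiltered-pl", "-o", "{quant_dir}"],
    "collate": ["alevin-fry", "collate", "-i", "{quant_dir}", "-r", "{map_dir}", "-t", "{threads}"],
    "quant": ["alevin-fry", "quant", "-i", "{quant_dir}", "-m", "{t2g}", "-r", "cr-like", "-t", "{threads}", "-o", "{quant_dir}", "--use-mtx"]
  }
}
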