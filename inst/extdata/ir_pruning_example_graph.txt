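# Eight-vertex splice graph illustrating the three pruning rules:
#   v3 is a full intron retention (immediately joint to v2 and v4, skipped
#      by the heavy edge v2->v4, weakly covered, no UMI support),
#   v5 is a partial intron retention presenting as a false alternative
#      first exon (adjacent to the source, reading through into v6 which
#      also receives the true junction from v4),
#   v7 is an isolated intronic vertex touching only source and sink.
# v1 is the true first exon, well supported by UMI reads.
chrom chr1
strand +
vertex 1 100 200 wv=6 wm=5
vertex 2 300 400 wv=8 wm=2
vertex 3 400 500 wv=1 wm=0
vertex 4 500 600 wv=9 wm=1
vertex 5 700 800 wv=1 wm=0
vertex 6 800 900 wv=7.5 wm=2
vertex 7 940 960 wv=4 wm=0
vertex 8 1000 1100 wv=7 wm=3
edge s 1 we=6
edge s 5 we=1
edge s 7 we=1
edge 1 2 we=9
edge 2 3 we=2
edge 2 4 we=10
edge 3 4 we=2
edge 4 6 we=8
edge 5 6 we=1
edge 6 8 we=7
edge 7 t we=1
edge 8 t we=7
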