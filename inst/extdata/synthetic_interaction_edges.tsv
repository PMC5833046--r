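node_a	node_b	score
ABCA1	ABCG1	0.669
ABCA1	ABCG2	0.525
ABCA1	SLC16A1	0.551
ABCA1	SLC16A3	0.792
ABCA1	SLC16A4	0.557
ABCA1	SLC27A2	0.601
ABCA1	SLC27A4	0.886
ABCA1	SLC2A1	0.685
ABCA1	SLC47A1	0.841
ABCG1	ABCG2	0.764
ABCG1	SLC16A1	0.72
ABCG1	SLC16A3	0.618
ABCG1	SLC16A4	0.628
ABCG1	SLC27A2	0.506
ABCG1	SLC27A4	0.83
ABCG1	SLC2A1	0.572
ABCG1	SLC47A1	0.684
ABCG1	SLC6A2	0.888
ABCG2	SLC16A1	0.875
ABCG2	SLC16A3	0.743
ABCG2	SLC16A4	0.501
ABCG2	SLC27A2	0.933
ABCG2	SLC2A1	0.501
LMBRD1	SLC19A1	0.822
LMBRD1	SLC19A3	0.619
LMBRD1	SLC23A2	0.533
LMBRD1	SLC23A3	0.691
LMBRD1	SLC46A1	0.911
SLC11A2	SLC26A2	0.918
SLC11A2	SLC30A1	0.546
SLC11A2	SLC30A2	0.625
SLC11A2	SLC30A4	0.631
SLC11A2	SLC39A1	0.708
SLC11A2	SLC39A8	0.553
SLC11A2	SLC5A5	0.651
SLC11A2	SLC9A1	0.561
SLC11A2	SLC9B2	0.926
SLC12A8	SLC38A1	0.826
SLC12A8	SLC38A2	0.706
SLC12A8	SLC3A2	0.765
SLC12A8	SLC7A1	0.932
SLC12A8	SLC7A5	0.705
SLC12A8	SLC7A6	0.718
SLC12A8	SLC7A7	0.788
SLC16A1	SLC16A3	0.69
SLC16A1	SLC16A4	0.931
SLC16A1	SLC27A2	0.73
SLC16A1	SLC27A4	0.555
SLC16A1	SLC2A1	0.9
SLC16A1	SLC6A2	0.611
SLC16A3	SLC16A4	0.618
SLC16A3	SLC27A4	0.526
SLC16A3	SLC2A1	0.693
SLC16A3	SLC47A1	0.503
SLC16A3	SLC6A2	0.795
SLC16A4	SLC27A2	0.652
SLC16A4	SLC27A4	0.854
SLC16A4	SLC2A1	0.501
SLC16A4	SLC47A1	0.677
SLC16A4	SLC6A2	0.681
SLC19A1	ABCA1	0.172
SLC19A1	SLC19A2	0.695
SLC19A1	SLC19A3	0.687
SLC19A1	SLC22A15	0.613
SLC19A1	SLC23A3	0.616
SLC19A1	SLC30A1	0.284
SLC19A1	SLC46A1	0.9
SLC19A1	SLC5A6	0.524
SLC19A2	ABCG1	0.152
SLC19A2	SLC19A3	0.926
SLC19A2	SLC22A15	0.567
SLC19A2	SLC23A1	0.58
SLC19A2	SLC23A2	0.752
SLC19A2	SLC23A3	0.774
SLC19A2	SLC30A2	0.325
SLC19A2	SLC46A1	0.501
SLC19A3	SLC22A15	0.769
SLC19A3	SLC23A1	0.769
SLC19A3	SLC46A1	0.593
SLC22A15	SLC23A1	0.9
SLC22A15	SLC23A2	0.526
SLC22A15	SLC23A3	0.86
SLC22A15	SLC46A1	0.801
SLC22A15	SLC5A6	0.939
SLC23A1	SLC23A2	0.861
SLC23A1	SLC23A3	0.736
SLC23A1	SLC46A1	0.51
SLC23A1	SLC5A6	0.591
SLC23A2	SLC23A3	0.739
SLC23A3	SLC46A1	0.622
SLC26A2	SLC26A4	0.916
SLC26A2	SLC30A1	0.528
SLC26A2	SLC30A2	0.742
SLC26A2	SLC30A4	0.567
SLC26A2	SLC39A1	0.913
SLC26A2	SLC39A8	0.513
SLC26A2	SLC5A5	0.579
SLC26A2	SLC9B2	0.766
SLC26A2	TRPV6	0.525
SLC26A4	SLC26A6	0.943
SLC26A4	SLC30A1	0.847
SLC26A4	SLC30A2	0.755
SLC26A4	SLC30A4	0.748
SLC26A4	SLC39A1	0.696
SLC26A4	SLC4A1	0.914
SLC26A4	SLC5A5	0.745
SLC26A4	SLC9A1	0.877
SLC26A4	SLC9B2	0.894
SLC26A4	TRPV6	0.737
SLC26A6	SLC30A1	0.81
SLC26A6	SLC30A2	0.655
SLC26A6	SLC39A1	0.596
SLC26A6	SLC39A8	0.732
SLC26A6	SLC4A1	0.714
SLC26A6	SLC5A5	0.625
SLC26A6	SLC9A1	0.698
SLC26A6	SLC9B2	0.823
SLC27A2	SLC27A4	0.605
SLC27A2	SLC2A1	0.662
SLC27A2	SLC47A1	0.575
SLC27A2	SLC6A2	0.78
SLC27A4	SLC2A1	0.682
SLC27A4	SLC47A1	0.712
SLC27A4	SLC6A2	0.503
SLC2A1	SLC47A1	0.936
SLC30A1	ABCA1	0.376
SLC30A1	SLC30A2	0.789
SLC30A1	SLC30A4	0.892
SLC30A1	SLC39A1	0.606
SLC30A1	SLC39A8	0.709
SLC30A1	SLC4A1	0.87
SLC30A1	SLC5A5	0.887
SLC30A1	TRPV6	0.784
SLC30A2	ABCG1	0.153
SLC30A2	SLC30A4	0.701
SLC30A2	SLC39A1	0.861
SLC30A2	SLC39A8	0.566
SLC30A2	SLC4A1	0.818
SLC30A2	SLC5A5	0.676
SLC30A2	SLC9A1	0.715
SLC30A2	SLC9B2	0.846
SLC30A4	SLC39A1	0.788
SLC30A4	SLC39A8	0.533
SLC30A4	SLC4A1	0.622
SLC30A4	SLC9B2	0.529
SLC30A4	TRPV6	0.732
SLC38A1	SLC38A2	0.8
SLC38A1	SLC38A5	0.946
SLC38A1	SLC3A2	0.723
SLC38A1	SLC7A11	0.607
SLC38A1	SLC7A5	0.817
SLC38A1	SLC7A6	0.85
SLC38A1	SLC7A7	0.543
SLC38A1	SLC7A8	0.714
SLC38A2	SLC38A5	0.88
SLC38A2	SLC7A11	0.859
SLC38A2	SLC7A5	0.91
SLC38A2	SLC7A6	0.837
SLC38A2	SLC7A7	0.776
SLC38A2	SLC7A8	0.522
SLC38A5	SLC3A2	0.814
SLC38A5	SLC7A1	0.763
SLC38A5	SLC7A11	0.734
SLC38A5	SLC7A6	0.783
SLC38A5	SLC7A7	0.731
SLC38A5	SLC7A8	0.632
SLC39A1	SLC39A8	0.669
SLC39A1	SLC4A1	0.516
SLC39A1	SLC5A5	0.925
SLC39A1	SLC9A1	0.514
SLC39A8	SLC4A1	0.947
SLC39A8	SLC9A1	0.918
SLC39A8	TRPV6	0.789
SLC3A2	ABCA1	0.242
SLC3A2	SLC19A1	0.267
SLC3A2	SLC30A1	0.375
SLC3A2	SLC7A1	0.853
SLC3A2	SLC7A11	0.779
SLC3A2	SLC7A5	0.672
SLC3A2	SLC7A6	0.78
SLC3A2	SLC7A7	0.772
SLC3A2	SLC7A8	0.884
SLC46A1	SLC5A6	0.786
SLC47A1	SLC6A2	0.846
SLC4A1	SLC5A5	0.874
SLC4A1	SLC9A1	0.542
SLC4A1	SLC9B2	0.884
SLC4A1	TRPV6	0.584
SLC5A5	SLC9A1	0.876
SLC5A5	SLC9B2	0.744
SLC5A5	TRPV6	0.712
SLC5A6	LMBRD1	0.612
SLC6A2	ABCA1	0.9
SLC7A1	ABCG1	0.197
SLC7A1	SLC19A2	0.178
SLC7A1	SLC30A2	0.275
SLC7A1	SLC7A11	0.916
SLC7A1	SLC7A5	0.823
SLC7A1	SLC7A7	0.623
SLC7A1	SLC7A8	0.803
SLC7A11	SLC7A5	0.924
SLC7A11	SLC7A6	0.907
SLC7A11	SLC7A7	0.785
SLC7A5	SLC7A6	0.848
SLC7A5	SLC7A7	0.694
SLC7A5	SLC7A8	0.719
SLC7A6	SLC7A7	0.801
SLC7A6	SLC7A8	0.89
SLC7A7	SLC7A8	0.611
SLC7A8	SLC12A8	0.87
SLC9A1	SLC9B2	0.609
SLC9A1	TRPV6	0.738
SLC9B2	TRPV6	0.891
TRPV6	SLC11A2	0.727
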