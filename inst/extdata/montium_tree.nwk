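(S.lebanonensis:0.5,(D.virilis:0.4,(D.ananassae:0.3,(D.melanogaster:0.25,((D.triauraria:0.08,(D.auraria:0.06,(D.rufa:0.05,D.pectinifera:0.05):0.01):0.02):0.07,(D.kanapiae:0.13,((D.kikkawai:0.05,D.leontia:0.05):0.06,((D.serrata:0.04,(D.bunnanda:0.03,(D.birchii:0.02,D.mayri:0.02):0.01):0.01):0.05,((D.punjabiensis:0.05,D.watanabei:0.05):0.03,((D.vulcana:0.04,D.bakoue:0.04):0.02,(D.jambulina:0.05,(D.seguyi:0.04,D.burlai:0.04):0.01):0.01):0.02):0.01):0.02):0.02):0.02):0.1):0.05):0.05):0.1);
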