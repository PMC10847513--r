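>ecoli_edd_synthetic Escherichia_coli_synthetic_standin proteobacteria
TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVLAHGFAANPDQEKLGVKNY
KMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRC
LNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRR
YSAGKAKVRQLYAGSKTMVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEG
YYMAQAEPGNHNFVHPCDARYMKLHWVNLKWRQDYLCTVWQTLFPVWWLSCEHAQYWNWG
NLHWCGKMGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFGQEKISNLQMCSQRTGWLPGA
MPLPRTRIEGLYSNSWDHDLLHWPLQMPDLWCHYMMAGLKNPVRAMIPQCGPDPSWSPPI
PGGIFKLMAREHMLIDPYSIDKSMPHVHFYVHTDSIWVLRNDYSLCIAPHMMPFCRFQFT
VTVHPCNDYIYQAQVCFLNDVVVRAIWIYWCYWMRVILCETNYWHKWMMNTCYHTEPWAT
ECIDPCEKMLQAAQYMKWFCKDNCSVTYIIWRGDAREKAMGYQKGNTMKVMWAMTTIMVA
GCQ
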