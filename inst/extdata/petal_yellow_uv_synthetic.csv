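"wavelength_nm","value"
300,0.0554950118572931
305,0.0604094525558529
310,0.0686535808526556
315,0.0816206377364084
320,0.100705209317447
325,0.126914422249147
330,0.160366198251823
335,0.199808838455644
340,0.242358724659938
345,0.283646666070602
350,0.318460770405567
355,0.341793869201291
360,0.350017481418381
365,0.341805740194636
370,0.318485843445838
375,0.283687752440234
380,0.242420430906501
385,0.199898082511773
390,0.160492984299272
395,0.127092960790538
400,0.10095550721967
405,0.081970734912784
410,0.0691426812097994
415,0.0610922940896474
420,0.0564479538639313
425,0.0540735000576225
430,0.0531505392097043
435,0.053164724717041
440,0.0538483610158913
445,0.0551175199293546
450,0.057023992450026
455,0.0597285425005062
460,0.0634941410731261
465,0.0686947555205532
470,0.0758343315333245
475,0.085569529450781
480,0.0987269106070505
485,0.116299766560681
490,0.139402193615702
495,0.169151829142255
500,0.206456395599042
505,0.251706066048951
510,0.304432723429803
515,0.363072345154029
520,0.425000000000133
525,0.486927654846758
530,0.545567276574366
535,0.598293933972504
540,0.643543604505466
545,0.680848171339314
550,0.710597808483412
555,0.733700242094706
560,0.751273123153502
565,0.764430595116825
570,0.774166103250342
575,0.781306680014665
580,0.786510342528431
585,0.790284704351978
590,0.7930130304912
595,0.794980361806786
600,0.79639643533463
605,0.797414411523827
610,0.798145532632524
615,0.798670284053906
620,0.799046737802689
625,0.7993167116042
630,0.799510275996835
635,0.799649032455775
640,0.79974848740215
645,0.799819766215386
650,0.799870848052161
655,0.79990745406801
660,0.799933685622486
665,0.799952482481188
670,0.799965951598473
675,0.799975602940268
680,0.799982518581619
685,0.799987473933614
690,0.799991024638744
695,0.79999356885082
700,0.799995391869048
705,0.799996698124139
710,0.79999763409961
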