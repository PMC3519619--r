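wavelength_nm	epsilon
450	62816
451	60621.3
452	58507
453	56474
454	54522.3
455	52651.9
456	50862.3
457	49152.9
458	47522.8
459	45970.9
460	44496
461	43096.1
462	41767
463	40504.3
464	39303.9
465	38161.8
466	37074.5
467	36038.7
468	35051.3
469	34109.3
470	33210
471	32351.6
472	31534.9
473	30761.3
474	30031.9
475	29347.6
476	28709.2
477	28117.6
478	27573.4
479	27077.3
480	26630
481	26230.7
482	25872.9
483	25549.1
484	25252.3
485	24975.8
486	24713.2
487	24458.4
488	24205.7
489	23949.3
490	23684
491	23406.2
492	23118.7
493	22825.6
494	22531
495	22238.7
496	21952.3
497	21675.3
498	21410.8
499	21162.1
500	20932
501	20723.2
502	20537.2
503	20375.3
504	20238.8
505	20129.1
506	20047.6
507	19995.8
508	19975.2
509	19987.6
510	20035
511	20120.3
512	20251
513	20435.8
514	20684.1
515	21006.4
516	21414.3
517	21921.1
518	22542.1
519	23295.3
520	24202
521	25281.3
522	26529.1
523	27932.7
524	29476
525	31137.4
526	32889
527	34695.3
528	36511.9
529	38286
530	39956
531	41470.2
532	42845.4
533	44123.4
534	45353.4
535	46592
536	47881
537	49180.2
538	50422.9
539	51535.9
540	52440.8
541	53056.9
542	53304
543	53126.9
544	52555.5
545	51646.3
546	50459.9
547	49057.8
548	47500
549	45843.5
550	44143.5
551	42449.4
552	40804.1
553	39244.4
554	37801
555	36500
556	35361.7
557	34395.9
558	33610.1
559	33012.6
560	32613
561	32426.2
562	32480.8
563	32813
564	33467.4
565	34500
566	35959.1
567	37808.1
568	39980.4
569	42393.3
570	44940
571	47493.6
572	49933.9
573	52129.9
574	53936.4
575	55201.6
576	55778.8
577	55540
578	54426.3
579	52556.2
580	50104
581	47203.5
582	43828
583	39960.2
584	35647
585	31000
586	26239.9
587	21763.9
588	17844
589	14589.4
590	12000
591	10000.9
592	8451.7
593	7236.6
594	6272.8
595	5500
596	4872.8
597	4354.1
598	3915.4
599	3535.9
600	3200
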