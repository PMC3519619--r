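wavelength_nm	epsilon
450	103292
451	100492.5
452	97742.1
453	95014.7
454	92287.4
455	89540
456	86755.2
457	83918.6
458	81018.9
459	78047.8
460	75000
461	71882.8
462	68739.8
463	65618.3
464	62558.4
465	59594.3
466	56753.6
467	54058.5
468	51526.5
469	49170.4
470	47000
471	45017.4
472	43206
473	41547
474	40023.5
475	38620.7
476	37325.4
477	36125.7
478	35011.1
479	33972.1
480	33000
481	32087.7
482	31230.8
483	30425.8
484	29669.4
485	28958.7
486	28290.8
487	27663.3
488	27073.8
489	26520
490	26000
491	25512.1
492	25055.6
493	24630.3
494	24235.6
495	23871.3
496	23537.3
497	23233.2
498	22959
499	22714.6
500	22500
501	22315.2
502	22160.2
503	22034.7
504	21938.9
505	21872.8
506	21836.6
507	21830.7
508	21855.5
509	21911.7
510	22000
511	22120.9
512	22273.4
513	22456.5
514	22668.8
515	22909.5
516	23177.3
517	23471.4
518	23790.5
519	24133.8
520	24500
521	24888.8
522	25302.6
523	25745.1
524	26219.9
525	26731.1
526	27283
527	27880.4
528	28528.5
529	29232.9
530	30000
531	30834.7
532	31734.5
533	32694.6
534	33709.3
535	34772
536	35875.3
537	37010.3
538	38167.2
539	39334.6
540	40500
541	41651.3
542	42783.5
543	43893.4
544	44977.9
545	46033.8
546	47058.2
547	48047.9
548	49000
549	49909
550	50758.6
551	51529.2
552	52200.4
553	52751.6
554	53162.1
555	53412
556	53489.2
557	53410.8
558	53202.3
559	52890
560	52500
561	52052
562	51539.5
563	50950.7
564	50274.1
565	49500
566	48629
567	47699.8
568	46757.7
569	45844.8
570	45000
571	44246.7
572	43557
573	42892.9
574	42218.4
575	41500
576	40712.9
577	39860
578	38950.7
579	37994.4
580	37000
581	35978.4
582	34949
583	33931.4
584	32943.3
585	32000
586	31102.9
587	30204.4
588	29250.6
589	28195.1
590	27000
591	25654.5
592	24219.3
593	22762.8
594	21341.5
595	20000
596	18764.7
597	17627.6
598	16574.9
599	15594.7
600	14677
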